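#' Tolerance schedule for ABC SMC
#'
#' Builds the strictly decreasing vector of acceptance tolerances, by default
#' the final tolerance times the multipliers `{5, 3, 2, 1.5, 1}`.
#'
#' @param final_epsilon tolerance of the last population (`> 0`).
#' @param multipliers decreasing multipliers ending in 1.
#' @return strictly decreasing numeric vector of tolerances.
#' @examples
#' tolerance_schedule(0.5)   # 2.5 1.5 1.0 0.75 0.5
#' @export
tolerance_schedule <- function(final_epsilon, multipliers = c(5, 3, 2, 1.5, 1)) {
  if (final_epsilon <= 0) stop("'final_epsilon' must be positive", call. = FALSE)
  E <- final_epsilon * multipliers
  if (any(diff(E) >= 0)) stop("schedule must be strictly decreasing",
                              call. = FALSE)
  E
}

# Split an observation table into the structures the ABC loops need:
# per-plant observation days plus the stacked feature matrix.
prepare_observations <- function(observations, weights) {
  obs <- as_root_observations(observations)
  ids <- unique(obs$plant_id)
  plants <- lapply(ids, function(id) {
    rows <- obs[obs$plant_id == id, ]
    list(id = id, days = rows$day)
  })
  feats <- c("n_branches", "primary_length_cm", "mean_lateral_length_cm")
  om <- as.matrix(obs[order(match(obs$plant_id, ids), obs$day), feats])
  list(plants = plants, matrix = om, weights = weights)
}

# One model replicate per observed plant, stacked in the observation order.
simulate_dataset_matrix <- function(model, theta, plants) {
  if (length(plants) == 1L)
    return(model_simulate_summary(model, theta, plants[[1L]]$days))
  do.call(rbind, lapply(plants, function(pl)
    model_simulate_summary(model, theta, pl$days)))
}

#' Rejection-sampling ABC
#'
#' Draws parameters from the prior, simulates one model plant per observed
#' plant recorded at the observed days, and accepts the draw when the summed
#' [dataset_distance()] falls below the tolerance `epsilon`. Inefficient but
#' exact ABC; the SMC sampler [abc_smc()] is preferred for tight tolerances.
#'
#' @param observations a summary table (see [as_root_observations()]).
#' @param model a [root_model()].
#' @param epsilon acceptance tolerance (`> 0`).
#' @param n_accept number of accepted parameter sets to collect.
#' @param weights per-feature distance weights.
#' @param max_attempts attempts cap; exceeding it raises a non-convergence
#'   error naming `epsilon`.
#' @param seed optional integer seed (local to the call).
#' @return an object of class `"abc_rejection"`: list with `theta` (matrix of
#'   accepted draws), `distance`, `attempts`, `epsilon`, `model`.
#' @export
abc_rejection <- function(observations, model, epsilon, n_accept = 500L,
                          weights = c(1, 1, 1), max_attempts = 1e7,
                          seed = NULL) {
  stopifnot(inherits(model, "root_model"), epsilon > 0, n_accept >= 1L)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  ob <- prepare_observations(observations, weights)
  pnames <- names(model$priors)
  theta_acc <- matrix(NA_real_, n_accept, length(pnames),
                      dimnames = list(NULL, pnames))
  dist_acc <- numeric(n_accept)
  n <- 0L; attempts <- 0
  while (n < n_accept) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop(sprintf(
        "ABC rejection did not converge: %d/%d acceptances after %g attempts at epsilon = %g",
        n, n_accept, max_attempts, epsilon), call. = FALSE)
    theta <- sample_prior(model$priors)
    sm <- simulate_dataset_matrix(model, theta, ob$plants)
    rho <- distance_matrix_rows(ob$matrix, sm, weights)
    if (rho < epsilon) {
      n <- n + 1L
      theta_acc[n, ] <- theta
      dist_acc[n] <- rho
    }
  }
  structure(list(theta = theta_acc, distance = dist_acc, attempts = attempts,
                 epsilon = epsilon, model = model, seed = seed),
            class = "abc_rejection")
}

#' @export
print.abc_rejection <- function(x, ...) {
  cat(sprintf(
    "Rejection ABC: %d accepted at epsilon = %g (%g attempts, rate %.3g)\n",
    nrow(x$theta), x$epsilon, x$attempts, nrow(x$theta) / x$attempts))
  invisible(x)
}

#' ABC sequential Monte Carlo with model selection
#'
#' Fits one or more candidate [root models][root_model] to longitudinal root
#' summary data by likelihood-free sequential Monte Carlo. A population of
#' `n_particles` weighted particles (each a model indicator plus a parameter
#' vector) is propagated through the decreasing tolerance schedule. In the
#' first population parameters are drawn from the priors; afterwards a model
#' is redrawn from the model prior at every proposal, a particle of that
#' model is resampled by weight from the previous population, perturbed with
#' the Gaussian kernel (sd `kernel_scale` times the prior width per
#' parameter), rejected if it leaves the prior box, and accepted when one
#' simulated replicate per observed plant yields a summed distance below the
#' current tolerance. Importance weights follow the standard SMC correction,
#' with the kernel mixture taken over the previous particles of the proposed
#' model, and are normalised within each model; the posterior probability of
#' a model in a population is its particle fraction.
#'
#' @inheritParams abc_rejection
#' @param models a [root_model()] or list of competing models.
#' @param schedule strictly decreasing tolerance vector (see
#'   [tolerance_schedule()]).
#' @param n_particles particles per population.
#' @param model_prior prior probability per model (default uniform).
#' @param kernel_scale perturbation kernel sd as a fraction of prior width.
#' @param verbose print per-population acceptance diagnostics.
#' @return an object of class `"root_abc"` with elements `populations` (one
#'   data frame per tolerance: `model`, parameter columns, `weight`,
#'   `distance`), `model_probabilities` (populations x models),
#'   `attempts`, `schedule`, `models`, `n_particles`, `seed`.
#' @seealso [posterior_summary()], [posterior_mode()], [write_results()]
#' @export
abc_smc <- function(observations, models, schedule, n_particles = 1000L,
                    model_prior = NULL, kernel_scale = 0.1,
                    weights = c(1, 1, 1), max_attempts = 1e7, seed = NULL,
                    verbose = FALSE) {
  if (inherits(models, "root_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1L), "root_model")))
  names(models) <- vapply(models, `[[`, character(1L), "name")
  if (anyDuplicated(names(models)))
    stop("competing models must have distinct names", call. = FALSE)
  if (any(diff(schedule) >= 0) || any(schedule <= 0))
    stop("'schedule' must be strictly decreasing and positive", call. = FALSE)
  if (is.null(model_prior)) {
    model_prior <- rep(1 / length(models), length(models))
    names(model_prior) <- names(models)
  }
  model_prior <- model_prior[names(models)]
  if (anyNA(model_prior) || any(model_prior < 0) ||
      abs(sum(model_prior) - 1) > 1e-8)
    stop("'model_prior' must be named non-negative probabilities summing to 1",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  ob <- prepare_observations(observations, weights)
  mnames <- names(models)
  all_params <- unique(unlist(lapply(models, function(m) names(m$priors))))
  ksd <- lapply(models, function(m) kernel_sd(m$priors, kernel_scale))
  pdens <- vapply(models, function(m) 1 / prod(prior_width(m$priors)),
                  numeric(1L))
  lo <- lapply(models, function(m) prior_lower(m$priors))
  hi <- lapply(models, function(m) prior_upper(m$priors))
  wid <- lapply(models, function(m) prior_width(m$priors))
  npar <- vapply(models, function(m) length(m$priors), integer(1L))

  populations <- vector("list", length(schedule))
  attempts <- numeric(length(schedule))
  model_probs <- matrix(0, length(schedule), length(models),
                        dimnames = list(NULL, mnames))
  prev <- NULL

  for (t in seq_along(schedule)) {
    eps <- schedule[t]
    part_model <- character(n_particles)
    part_theta <- matrix(NA_real_, n_particles, length(all_params),
                         dimnames = list(NULL, all_params))
    part_w <- numeric(n_particles)
    part_d <- numeric(n_particles)
    if (t > 1L) {
      prev_idx <- lapply(mnames, function(m) which(prev$model == m))
      names(prev_idx) <- mnames
      alive <- mnames[lengths(prev_idx) > 0L]
      if (length(alive) < length(mnames) && verbose)
        message("population ", t, ": model(s) without surviving particles: ",
                paste(setdiff(mnames, alive), collapse = ", "))
      aprior <- model_prior[alive] / sum(model_prior[alive])
      prev_theta <- lapply(mnames, function(m)
        prev$theta[prev_idx[[m]], names(models[[m]]$priors), drop = FALSE])
      names(prev_theta) <- mnames
      prev_w <- lapply(mnames, function(m) prev$weight[prev_idx[[m]]])
      names(prev_w) <- mnames
      prev_cw <- lapply(prev_w, cumsum)  # for fast weighted resampling
    }
    i <- 0L; att <- 0
    while (i < n_particles) {
      att <- att + 1
      if (att > max_attempts)
        stop(sprintf(
          "ABC SMC did not converge: %d/%d particles after %g attempts at epsilon = %g (population %d)",
          i, n_particles, max_attempts, eps, t), call. = FALSE)
      if (t == 1L) {
        m <- if (length(mnames) == 1L) mnames
             else mnames[sample.int(length(mnames), 1L, prob = model_prior)]
        theta <- lo[[m]] + wid[[m]] * stats::runif(npar[[m]])
      } else {
        m <- if (length(alive) == 1L) alive
             else alive[sample.int(length(alive), 1L, prob = aprior)]
        cw <- prev_cw[[m]]
        j <- findInterval(stats::runif(1L) * cw[length(cw)], cw) + 1L
        theta <- prev_theta[[m]][j, ] +
          stats::rnorm(npar[[m]], 0, ksd[[m]])
        if (any(theta < lo[[m]] | theta > hi[[m]])) next  # prior density 0
      }
      sm <- simulate_dataset_matrix(models[[m]], theta, ob$plants)
      rho <- distance_matrix_rows(ob$matrix, sm, weights)
      if (rho >= eps) next
      i <- i + 1L
      part_model[i] <- m
      part_theta[i, names(theta)] <- theta
      part_d[i] <- rho
      if (t == 1L) {
        part_w[i] <- 1
      } else {
        th_prev <- prev_theta[[m]]
        ld <- 0
        for (k in seq_along(ksd[[m]]))
          ld <- ld + stats::dnorm(theta[k] - th_prev[, k], 0, ksd[[m]][k],
                                  log = TRUE)
        part_w[i] <- pdens[[m]] / sum(prev_w[[m]] * exp(ld))
      }
    }
    # per-model weight normalisation
    for (m in unique(part_model)) {
      sel <- part_model == m
      part_w[sel] <- part_w[sel] / sum(part_w[sel])
    }
    tab <- table(factor(part_model, levels = mnames))
    model_probs[t, ] <- as.numeric(tab) / n_particles
    attempts[t] <- att
    prev <- list(model = part_model, theta = part_theta, weight = part_w)
    populations[[t]] <- data.frame(population = t, model = part_model,
                                   part_theta, weight = part_w,
                                   distance = part_d)
    if (verbose)
      message(sprintf(
        "population %d: epsilon = %g, %d particles, %g attempts (rate %.3g)",
        t, eps, n_particles, att, n_particles / att))
  }

  structure(list(populations = populations,
                 model_probabilities = model_probs,
                 attempts = attempts, schedule = schedule, models = models,
                 model_prior = model_prior, n_particles = n_particles,
                 kernel_scale = kernel_scale, weights = weights,
                 seed = seed, call = match.call()),
            class = "root_abc")
}
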