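final_population <- function(object) {
  object$populations[[length(object$populations)]]
}

map_model <- function(object) {
  probs <- object$model_probabilities[nrow(object$model_probabilities), ]
  names(probs)[which.max(probs)]
}

# weighted quantile (inverse of the weighted empirical CDF)
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1L))
}

#' Weighted posterior summaries of an ABC SMC fit
#'
#' Per-parameter weighted mean, standard deviation and credible interval of
#' the final (or any) population for one model.
#'
#' @param object a `"root_abc"` fit from [abc_smc()].
#' @param model model name; default the model with the highest final
#'   posterior probability.
#' @param population population index (default the final one).
#' @param level credible-interval coverage (default 0.95).
#' @return data frame with one row per parameter: `mean`, `sd`, `lower`,
#'   `median`, `upper`.
#' @export
posterior_summary <- function(object, model = NULL, population = NULL,
                              level = 0.95) {
  stopifnot(inherits(object, "root_abc"))
  if (is.null(population)) population <- length(object$populations)
  pop <- object$populations[[population]]
  if (is.null(model)) model <- map_model(object)
  if (!model %in% pop$model)
    stop("model '", model, "' has no particles in population ", population,
         call. = FALSE)
  sel <- pop$model == model
  pars <- names(object$models[[model]]$priors)
  w <- pop$weight[sel]
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- pop[[p]][sel]
    mu <- sum(w * x) / sum(w)
    sdv <- sqrt(sum(w * (x - mu)^2) / sum(w))
    q <- wquantile(x, w, c(a, 0.5, 1 - a))
    data.frame(parameter = p, mean = mu, sd = sdv,
               lower = q[1L], median = q[2L], upper = q[3L])
  }))
  rownames(out) <- NULL
  attr(out, "model") <- model
  attr(out, "level") <- level
  out
}

#' Weighted posterior mode of one parameter
#'
#' Mode of the weighted histogram of a parameter's marginal posterior in the
#' final (or any) population: the midpoint of the bin carrying the most
#' weight.
#'
#' @inheritParams posterior_summary
#' @param parameter parameter name.
#' @param bins number of histogram bins.
#' @return the modal value (scalar).
#' @export
posterior_mode <- function(object, parameter, model = NULL,
                           population = NULL, bins = 30L) {
  stopifnot(inherits(object, "root_abc"))
  if (is.null(population)) population <- length(object$populations)
  pop <- object$populations[[population]]
  if (is.null(model)) model <- map_model(object)
  sel <- pop$model == model
  if (!any(sel))
    stop("model '", model, "' has no particles in population ", population,
         call. = FALSE)
  x <- pop[[parameter]][sel]
  if (is.null(x)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  w <- pop$weight[sel]
  r <- range(x)
  if (diff(r) < 1e-12) return(mean(r))
  br <- seq(r[1L], r[2L], length.out = bins + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  wsum <- vapply(seq_len(bins), function(k) sum(w[bin == k]), numeric(1L))
  k <- which.max(wsum)
  (br[k] + br[k + 1L]) / 2
}

#' Posterior model probabilities per population
#'
#' @param object a `"root_abc"` fit.
#' @return matrix (populations x models) of particle fractions.
#' @export
model_probabilities <- function(object) {
  stopifnot(inherits(object, "root_abc"))
  object$model_probabilities
}

#' @export
print.root_abc <- function(x, ...) {
  cat(sprintf("ABC SMC fit: %d model(s), %d particles, %d populations\n",
              length(x$models), x$n_particles, length(x$schedule)))
  cat("  tolerance schedule:", paste(signif(x$schedule, 4), collapse = " "),
      "\n")
  probs <- x$model_probabilities[nrow(x$model_probabilities), ]
  cat("  final model probabilities:",
      paste(sprintf("%s = %.3f", names(probs), probs), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.root_abc <- function(object, level = 0.95, ...) {
  probs <- object$model_probabilities[nrow(object$model_probabilities), ]
  tabs <- lapply(names(object$models)[probs > 0], function(m)
    posterior_summary(object, model = m, level = level))
  names(tabs) <- names(object$models)[probs > 0]
  structure(list(model_probabilities = object$model_probabilities,
                 posterior = tabs, attempts = object$attempts,
                 schedule = object$schedule,
                 n_particles = object$n_particles, level = level),
            class = "summary.root_abc")
}

#' @export
print.summary.root_abc <- function(x, ...) {
  cat("ABC SMC posterior summary\n\n")
  cat("Model probabilities by population:\n")
  print(round(x$model_probabilities, 3))
  cat(sprintf("\nAcceptance: %s attempts over populations %s\n",
              paste(format(x$attempts, big.mark = ","), collapse = ", "),
              paste(signif(x$schedule, 3), collapse = " > ")))
  for (m in names(x$posterior)) {
    cat(sprintf("\nModel '%s' (final population, %g%% credible interval):\n",
                m, 100 * x$level))
    print(x$posterior[[m]], digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.root_abc <- function(object, model = NULL, ...) {
  ps <- posterior_summary(object, model = model)
  stats::setNames(ps$mean, ps$parameter)
}

#' Marginal posterior histograms of an ABC SMC fit
#'
#' Weighted histograms of each free parameter of one model in the final
#' population.
#'
#' @param x a `"root_abc"` fit.
#' @param model model name (default the highest-probability model).
#' @param bins number of histogram bins.
#' @param ... ignored.
#' @export
plot.root_abc <- function(x, model = NULL, bins = 30L, ...) {
  pop <- final_population(x)
  if (is.null(model)) model <- map_model(x)
  sel <- pop$model == model
  pars <- names(x$models[[model]]$priors)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)))
  on.exit(graphics::par(old))
  for (p in pars) {
    xx <- pop[[p]][sel]; w <- pop$weight[sel]
    r <- range(xx)
    if (diff(r) < 1e-12) r <- r + c(-1, 1) * max(1e-6, abs(r[1L]) * 1e-3)
    br <- seq(r[1L], r[2L], length.out = bins + 1L)
    bin <- findInterval(xx, br, rightmost.closed = TRUE, all.inside = TRUE)
    h <- vapply(seq_len(bins), function(k) sum(w[bin == k]), numeric(1L))
    graphics::barplot(h / sum(h), names.arg = signif((br[-1L] + br[-(bins + 1L)]) / 2, 2),
                      main = p, ylab = "posterior weight", border = NA,
                      space = 0)
  }
  invisible(x)
}

#' Posterior predictive simulation from a fitted model
#'
#' Draws particles (by weight) from the final population of one model and
#' simulates a root-system summary table from each, at the requested
#' observation days.
#'
#' @param object a `"root_abc"` fit.
#' @param nsim number of posterior draws.
#' @param seed optional integer seed (local to the call).
#' @param days observation days for the simulated plants.
#' @param model model name (default the highest-probability model).
#' @param ... ignored.
#' @return list of `nsim` summary data frames.
#' @export
simulate.root_abc <- function(object, nsim = 1L, seed = NULL,
                              days = c(2, 5, 7, 10), model = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  pop <- final_population(object)
  if (is.null(model)) model <- map_model(object)
  sel <- which(pop$model == model)
  if (!length(sel)) stop("model '", model, "' absent from final population",
                         call. = FALSE)
  w <- pop$weight[sel]
  pars <- names(object$models[[model]]$priors)
  lapply(seq_len(nsim), function(i) {
    j <- sel[sample.int(length(sel), 1L, prob = w)]
    theta <- stats::setNames(as.numeric(pop[j, pars]), pars)
    sm <- model_simulate_summary(object$models[[model]], theta, days)
    data.frame(plant_id = sprintf("sim%d", i), day = days, sm)
  })
}
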