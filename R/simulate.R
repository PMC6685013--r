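# unchecked elongation, hot path of the ABC loops
elong_fast <- function(elapsed, rate, l_max, law) {
  if (law == "linear" || is.infinite(l_max)) rate * elapsed
  else -l_max * expm1(-rate * elapsed / l_max)
}

# Gillespie event times of a rate-b Poisson process on [0, horizon],
# drawn as cumulative exponential waiting times.
poisson_event_times <- function(b, horizon) {
  if (b <= 0) return(numeric())
  n <- ceiling(b * horizon + 6 * sqrt(b * horizon) + 10)
  t <- cumsum(stats::rexp(n, b))
  while (t[length(t)] <= horizon)
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n, b)))
  t[t <= horizon]
}

# Event generation shared by the public simulator and the fast summary path.
# Returns list(position, t_init) of branching events up to `horizon`.
branch_events <- function(growth, branching, law, horizon) {
  g <- growth$g; l_max <- growth$l_max
  if (branching$kind == "fixed_spacing") {
    tip <- elong_fast(horizon, g, l_max, law)
    if (branching$b_max < 1 || tip < branching$d)
      return(list(position = numeric(), t_init = numeric()))
    n_cap <- min(branching$b_max, ceiling(tip / branching$d) + 5L)
    if (branching$spacing_cv > 0) {
      gaps <- branching$d * (1 + branching$spacing_cv * stats::rnorm(n_cap))
      bad <- which(gaps <= 0)
      for (i in bad) {  # truncate multiplicative noise at zero
        repeat {
          gap <- branching$d * (1 + branching$spacing_cv * stats::rnorm(1L))
          if (gap > 0) break
        }
        gaps[i] <- gap
      }
      # noisy gaps can undershoot the tip with the deterministic cap; extend
      while (sum(gaps) <= tip && length(gaps) < branching$b_max) {
        repeat {
          gap <- branching$d * (1 + branching$spacing_cv * stats::rnorm(1L))
          if (gap > 0) break
        }
        gaps <- c(gaps, gap)
      }
    } else {
      gaps <- rep(branching$d, n_cap)
    }
    pos <- cumsum(gaps)
    pos <- pos[pos <= tip]
    if (length(pos) > branching$b_max) pos <- pos[seq_len(branching$b_max)]
    return(list(position = pos,
                t_init = time_to_length(pos, g, l_max, law)))
  }
  b <- branching$b
  if (branching$kind == "uniform") {
    # positions are history-independent: fully vectorised
    t_init <- poisson_event_times(b, horizon)
    pos <- stats::runif(length(t_init)) * elong_fast(t_init, g, l_max, law)
    return(list(position = pos, t_init = t_init))
  }
  # min_separation: sequential, each event sees the branches before it
  pos <- numeric(); t_init <- numeric()
  for (t in poisson_event_times(b, horizon)) {
    p <- stats::runif(1L, 0, elong_fast(t, g, l_max, law))
    if (length(pos) && any(abs(p - pos) < branching$delta))
      next  # event consumed, no branch implemented
    pos <- c(pos, p)
    t_init <- c(t_init, t)
  }
  list(position = pos, t_init = t_init)
}

# Fast path used inside ABC loops: matrix with one row per observation day,
# columns n_branches, primary_length_cm, mean_lateral_length_cm.
simulate_summary_matrix <- function(g, l_max, alpha, law, branching, days) {
  growth <- list(g = g, l_max = l_max, alpha = alpha)
  ev <- branch_events(growth, branching, law, max(days))
  out <- matrix(0, nrow = length(days), ncol = 3L,
                dimnames = list(NULL, c("n_branches", "primary_length_cm",
                                        "mean_lateral_length_cm")))
  out[, 2L] <- elong_fast(days, g, l_max, law)
  if (length(ev$t_init)) {
    lr <- alpha * g
    for (j in seq_along(days)) {
      sel <- ev$t_init <= days[j]
      if (any(sel)) {
        out[j, 1L] <- sum(sel)
        out[j, 3L] <- mean(elong_fast(days[j] - ev$t_init[sel], lr, l_max,
                                      law))
      }
    }
  }
  out
}

#' Simulate a stochastic root system over time
#'
#' Hybrid stochastic-deterministic simulation: the primary root elongates
#' deterministically under the chosen growth law while lateral branches are
#' placed by the branching model -- Poisson (Gillespie) events placed
#' uniformly or with a minimum-separation rule, or deterministic emergence at
#' fixed spacings. Once initiated, a lateral elongates under the same law
#' with rate `alpha * g`, its clock starting at the branching event.
#' Branching is restricted to the primary root; laterals never branch.
#'
#' @param growth a [growth_parameters()] object.
#' @param branching a [branching model][branching_models].
#' @param times strictly increasing positive observation times, days.
#' @param law growth law, `"negative_exponential"` or `"linear"`.
#' @param seed optional integer; if given, the simulation is reproducible and
#'   the caller's RNG state is left untouched.
#' @return an object of class `"root_system"`: a list of snapshots (one per
#'   observation time), each of class `"root_snapshot"` with fields `time`,
#'   `primary_length` and a `branches` data frame (`position`, `t_init`,
#'   `length`). The branch set is cumulative over time.
#' @examples
#' sys <- simulate_root_system(growth_parameters(0.49, 20, 0.16),
#'                             uniform_branching(0.6), times = c(5, 10, 15),
#'                             seed = 1)
#' summarize_system(sys)
#' @export
simulate_root_system <- function(growth, branching, times,
                                 law = c("negative_exponential", "linear"),
                                 seed = NULL) {
  law <- match.arg(law)
  stopifnot(inherits(growth, "growth_parameters"),
            inherits(branching, "branching_model"))
  if (!length(times) || any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be a non-empty strictly increasing positive sequence",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  ev <- branch_events(growth, branching, law, max(times))
  snaps <- lapply(times, function(tt) {
    sel <- ev$t_init <= tt
    br <- data.frame(position = ev$position[sel], t_init = ev$t_init[sel])
    br$length <- if (nrow(br))
      elongate(tt - br$t_init, growth$alpha * growth$g, growth$l_max, law)
    else numeric()
    structure(list(time = tt,
                   primary_length = elongate(tt, growth$g, growth$l_max, law),
                   branches = br),
              class = "root_snapshot")
  })
  structure(list(snapshots = snaps, growth = growth, branching = branching,
                 law = law, seed = seed),
            class = "root_system")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' @export
print.root_system <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf(
    "Simulated root system (%s law, %s branching): %d snapshot(s),\n",
    x$law, x$branching$kind, length(x$snapshots)))
  cat(sprintf("  at day %g: primary %.3f cm, %d lateral branch(es)\n",
              last$time, last$primary_length, nrow(last$branches)))
  invisible(x)
}

#' @export
print.root_snapshot <- function(x, ...) {
  cat(sprintf("Root snapshot at day %g: primary %.3f cm, %d branch(es)\n",
              x$time, x$primary_length, nrow(x$branches)))
  invisible(x)
}
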