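#' Branching models for lateral root placement
#'
#' Three mechanisms decide when and where first-order laterals appear on the
#' primary root.
#'
#' * `uniform_branching(b)`: branching is a Poisson process in time with rate
#'   `b` per day; each event places a lateral uniformly along the current
#'   primary length.
#' * `min_separation_branching(b, delta)`: as above, but a proposed position
#'   falling within `delta` cm of an existing branch is discarded (the Poisson
#'   event is consumed and no branch is added).
#' * `fixed_spacing_branching(d, b_max, spacing_cv)`: laterals emerge
#'   deterministically at spacings of `d` cm along the primary, each
#'   initiating at the moment the primary tip first passes its position, up
#'   to at most `b_max` branches. `spacing_cv` adds multiplicative Gaussian
#'   noise (coefficient of variation) to each inter-lateral gap, truncated to
#'   stay positive; with the default 0 the spacings are exact multiples of
#'   `d`.
#'
#' @param b branching rate, events per day (`>= 0`).
#' @param delta exclusion radius around existing branches, cm (`>= 0`).
#' @param d inter-lateral spacing, cm (`> 0`).
#' @param b_max maximum number of lateral branches (`>= 0`).
#' @param spacing_cv coefficient of variation of the gaps (`>= 0`).
#' @return an object of classes `c("<kind>_branching", "branching_model")`.
#' @name branching_models
NULL

#' @rdname branching_models
#' @export
uniform_branching <- function(b) {
  if (b < 0) stop("'b' must be non-negative", call. = FALSE)
  structure(list(kind = "uniform", b = b),
            class = c("uniform_branching", "branching_model"))
}

#' @rdname branching_models
#' @export
min_separation_branching <- function(b, delta) {
  if (b < 0) stop("'b' must be non-negative", call. = FALSE)
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
  structure(list(kind = "min_separation", b = b, delta = delta),
            class = c("min_separation_branching", "branching_model"))
}

#' @rdname branching_models
#' @export
fixed_spacing_branching <- function(d, b_max = Inf, spacing_cv = 0) {
  if (d <= 0) stop("'d' must be positive", call. = FALSE)
  if (b_max < 0) stop("'b_max' must be non-negative", call. = FALSE)
  if (spacing_cv < 0) stop("'spacing_cv' must be non-negative", call. = FALSE)
  structure(list(kind = "fixed_spacing", d = d, b_max = b_max,
                 spacing_cv = spacing_cv),
            class = c("fixed_spacing_branching", "branching_model"))
}

#' @export
print.branching_model <- function(x, ...) {
  fields <- x[setdiff(names(x), "kind")]
  cat(sprintf("Branching model '%s' (%s)\n", x$kind,
              paste(sprintf("%s = %g", names(fields), unlist(fields)),
                    collapse = ", ")))
  invisible(x)
}

#' Waiting time to the next Poisson branching event
#'
#' Gillespie draw: exponentially distributed with mean `1/b`. A zero rate
#' schedules no event (`Inf`).
#'
#' @param b branching rate, events per day (`>= 0`).
#' @return waiting time in days.
#' @export
next_branch_interval <- function(b) {
  if (b < 0) stop("'b' must be non-negative", call. = FALSE)
  if (b == 0) return(Inf)
  stats::rexp(1L, rate = b)
}

#' Place one lateral branch on the primary root
#'
#' Applies a branching model's placement rule given the current primary
#' length and the positions of existing branches. Returns the new branch
#' position in cm, or `NA_real_` when the model rejects the event (a uniform
#' proposal within `delta` of an existing branch under minimum separation; no
#' free spacing multiple below the tip, or the `b_max` cap, under fixed
#' spacing).
#'
#' @param model a [branching model][branching_models].
#' @param primary_length current primary root length, cm (`>= 0`).
#' @param existing numeric vector of existing branch positions, cm.
#' @return position in cm, or `NA_real_` on rejection.
#' @export
place_branch <- function(model, primary_length, existing = numeric()) {
  UseMethod("place_branch")
}

#' @export
place_branch.uniform_branching <- function(model, primary_length,
                                           existing = numeric()) {
  if (primary_length < 0) stop("'primary_length' must be non-negative",
                               call. = FALSE)
  stats::runif(1L, 0, primary_length)
}

#' @export
place_branch.min_separation_branching <- function(model, primary_length,
                                                  existing = numeric()) {
  if (primary_length < 0) stop("'primary_length' must be non-negative",
                               call. = FALSE)
  pos <- stats::runif(1L, 0, primary_length)
  if (length(existing) && any(abs(pos - existing) < model$delta))
    return(NA_real_)
  pos
}

#' @export
place_branch.fixed_spacing_branching <- function(model, primary_length,
                                                 existing = numeric()) {
  if (primary_length < 0) stop("'primary_length' must be non-negative",
                               call. = FALSE)
  if (length(existing) >= model$b_max) return(NA_real_)
  k <- 1L
  repeat {
    pos <- k * model$d
    if (pos > primary_length) return(NA_real_)
    if (!length(existing) || min(abs(existing - pos)) > 1e-9) return(pos)
    k <- k + 1L
  }
}
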