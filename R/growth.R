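#' Deterministic root elongation laws
#'
#' Length of a root that has been elongating for `elapsed` days at rate
#' `rate`. Two laws are supported: the saturating negative-exponential law
#' \deqn{l(t) = l_{max}\,(1 - e^{-g t / l_{max}})}{l(t) = l_max (1 - exp(-g t / l_max))}
#' in which growth starts at rate `rate` and decelerates towards the
#' asymptote `l_max`, and the linear law \eqn{l(t) = g t}, which ignores
#' `l_max`. The same laws describe primary and lateral roots; a lateral's
#' `rate` is the primary rate scaled by the lateral factor \eqn{\alpha}, and
#' its `elapsed` time is measured from its own branching event.
#'
#' @param elapsed time since the root initiated, days (vectorised, `>= 0`).
#' @param rate initial elongation rate, cm/day (`>= 0`).
#' @param l_max asymptotic length scale, cm (`> 0`); unused by the linear law.
#' @param law `"negative_exponential"` or `"linear"`.
#' @return root length in cm, same length as `elapsed`.
#' @examples
#' elongate(15, rate = 0.49, l_max = 20)           # approx 6.15 cm
#' elongate(2, rate = 1, law = "linear")           # exactly 2 cm
#' @export
elongate <- function(elapsed, rate, l_max = Inf,
                     law = c("negative_exponential", "linear")) {
  law <- match.arg(law)
  if (any(elapsed < 0)) stop("'elapsed' must be non-negative", call. = FALSE)
  if (length(rate) != 1L || is.na(rate) || rate < 0)
    stop("'rate' must be a single non-negative number", call. = FALSE)
  if (law == "linear") return(rate * elapsed)
  if (!is.finite(l_max) || l_max <= 0) {
    if (is.infinite(l_max)) return(rate * elapsed)  # exact Taylor limit
    stop("'l_max' must be positive", call. = FALSE)
  }
  # expm1 keeps precision in the near-linear regime l_max >> g t
  -l_max * expm1(-rate * elapsed / l_max)
}

#' Time for a root to reach a given length
#'
#' Inverse of [elongate()] in time. Under the negative-exponential law a
#' length at or beyond the `l_max` asymptote is never reached and `Inf` is
#' returned; a zero rate likewise yields `Inf` for positive lengths.
#'
#' @inheritParams elongate
#' @param length target length, cm (vectorised, `>= 0`).
#' @return time in days at which the root first attains `length`.
#' @export
time_to_length <- function(length, rate, l_max = Inf,
                           law = c("negative_exponential", "linear")) {
  law <- match.arg(law)
  if (any(length < 0)) stop("'length' must be non-negative", call. = FALSE)
  if (rate < 0) stop("'rate' must be non-negative", call. = FALSE)
  if (rate == 0) return(ifelse(length > 0, Inf, 0))
  if (law == "linear" || is.infinite(l_max)) return(length / rate)
  out <- rep(Inf, length(length))
  ok <- length < l_max
  out[ok] <- -(l_max / rate) * log1p(-length[ok] / l_max)
  out
}

#' Growth parameters of a root system
#'
#' Bundles the primary elongation rate `g`, the asymptotic length scale
#' `l_max` and the dimensionless lateral scaling `alpha`. Laterals elongate
#' under the same law as the primary with rate `alpha * g` and the same
#' `l_max`, their clocks starting at their branching events.
#'
#' @param g primary elongation rate, cm/day (`>= 0`).
#' @param l_max asymptotic length scale, cm (`> 0`).
#' @param alpha lateral rate scaling in `[0, 1]`.
#' @return an object of class `"growth_parameters"`.
#' @export
growth_parameters <- function(g, l_max = Inf, alpha = 0) {
  if (g < 0) stop("'g' must be non-negative", call. = FALSE)
  if (l_max <= 0) stop("'l_max' must be positive", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]", call. = FALSE)
  structure(list(g = g, l_max = l_max, alpha = alpha),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf("Growth parameters: g = %g cm/day, l_max = %g cm, alpha = %g\n",
              x$g, x$l_max, x$alpha))
  invisible(x)
}
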