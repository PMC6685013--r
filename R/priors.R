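#' Uniform parameter priors
#'
#' Independent uniform priors over named parameters, each given as a
#' `c(lower, upper)` interval. [default_priors()] returns the standard box
#' used throughout: `g` in (0, 1.4) cm/day, `b` in (0, 1.4) /day, `alpha` in
#' (0, 1) and `l_max` in (5, 40) cm.
#'
#' @param ... named length-2 numeric vectors, `lower < upper`.
#' @return an object of class `"abc_priors"` (named list of intervals).
#' @examples
#' abc_priors(g = c(0, 1.4), d = c(0.1, 3))
#' @export
abc_priors <- function(...) {
  pr <- list(...)
  if (!length(pr) || is.null(names(pr)) || any(!nzchar(names(pr))))
    stop("priors must be named", call. = FALSE)
  for (nm in names(pr)) {
    iv <- pr[[nm]]
    if (length(iv) != 2L || !is.numeric(iv) || iv[1L] >= iv[2L])
      stop("prior '", nm, "' must be c(lower, upper) with lower < upper",
           call. = FALSE)
  }
  structure(pr, class = "abc_priors")
}

#' @rdname abc_priors
#' @export
default_priors <- function() {
  abc_priors(g = c(0, 1.4), b = c(0, 1.4), alpha = c(0, 1), l_max = c(5, 40))
}

#' @export
print.abc_priors <- function(x, ...) {
  cat("Uniform priors:\n")
  for (nm in names(x))
    cat(sprintf("  %-6s ~ U(%g, %g)\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

prior_lower <- function(prior) vapply(prior, `[`, numeric(1L), 1L)
prior_upper <- function(prior) vapply(prior, `[`, numeric(1L), 2L)
prior_width <- function(prior) prior_upper(prior) - prior_lower(prior)

#' Draw parameter vectors from a uniform prior
#'
#' @param prior an [abc_priors()] object.
#' @param n number of draws.
#' @return for `n = 1` a named numeric vector; otherwise an `n` x p matrix
#'   with one column per parameter.
#' @export
sample_prior <- function(prior, n = 1L) {
  stopifnot(inherits(prior, "abc_priors"))
  lo <- prior_lower(prior); w <- prior_width(prior)
  m <- matrix(stats::runif(n * length(prior)), nrow = n)
  m <- sweep(sweep(m, 2L, w, "*"), 2L, lo, "+")
  colnames(m) <- names(prior)
  if (n == 1L) m[1L, ] else m
}

#' Uniform prior density
#'
#' Constant `1 / prod(widths)` inside the prior box and exactly 0 outside.
#'
#' @param prior an [abc_priors()] object.
#' @param theta named parameter vector (must cover the prior's names).
#' @return density value.
#' @export
prior_density <- function(prior, theta) {
  stopifnot(inherits(prior, "abc_priors"))
  th <- theta[names(prior)]
  if (anyNA(th)) stop("theta lacks parameters: ",
                      paste(names(prior)[is.na(th)], collapse = ", "),
                      call. = FALSE)
  inside <- all(th >= prior_lower(prior) & th <= prior_upper(prior))
  if (inside) 1 / prod(prior_width(prior)) else 0
}

#' Gaussian perturbation kernel
#'
#' The SMC perturbation kernel adds independent zero-mean Gaussian noise to
#' each parameter with standard deviation `scale` times that parameter's
#' prior width (default `0.1 * P`). The kernel is symmetric and is not
#' adapted across populations.
#'
#' @param prior an [abc_priors()] object.
#' @param scale kernel standard deviation as a fraction of the prior width.
#' @return named vector of per-parameter standard deviations.
#' @export
kernel_sd <- function(prior, scale = 0.1) {
  stopifnot(inherits(prior, "abc_priors"), scale > 0)
  scale * prior_width(prior)
}

#' Perturb a parameter vector
#'
#' @param theta named parameter vector.
#' @param sd per-parameter kernel standard deviations (from [kernel_sd()]).
#' @return perturbed vector; may fall outside the prior support (the SMC
#'   rejects such proposals via the zero prior density).
#' @export
perturb <- function(theta, sd) {
  nm <- names(sd)
  theta[nm] <- theta[nm] + stats::rnorm(length(nm), 0, sd)
  theta
}

#' Perturbation kernel density
#'
#' Product of component-wise Gaussian densities for a move from `theta_from`
#' to `theta_to`; strictly positive and symmetric in its arguments.
#'
#' @param sd per-parameter kernel standard deviations.
#' @param theta_from,theta_to named parameter vectors.
#' @return density value.
#' @export
kernel_density <- function(sd, theta_from, theta_to) {
  nm <- names(sd)
  prod(stats::dnorm(theta_to[nm] - theta_from[nm], 0, sd))
}
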