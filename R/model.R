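#' Specify a candidate root growth model for inference
#'
#' Combines a growth law, a branching mechanism, uniform priors over the
#' model's free parameters and optional fixed parameter values into a unit
#' that [abc_smc()] and [abc_rejection()] can simulate from. Free parameters
#' (those named in `priors`) are inferred; `fixed` parameters are held
#' constant.
#'
#' Parameter names understood by the simulator: `g`, `l_max`, `alpha`
#' (growth; `l_max` is ignored by the linear law and defaults to `Inf`,
#' `alpha` defaults to 0), `b` (Poisson branching rate), `delta` (minimum
#' separation), `d` and `b_max` (fixed spacing; `b_max` defaults to `Inf`).
#'
#' @param law `"negative_exponential"` or `"linear"`.
#' @param branching `"uniform"`, `"min_separation"` or `"fixed_spacing"`.
#' @param priors an [abc_priors()] object over the free parameters.
#' @param fixed named list of fixed parameter values.
#' @param name model label used in results (defaults to `"law/branching"`).
#' @return an object of class `"root_model"`.
#' @examples
#' m <- root_model("negative_exponential", "uniform",
#'                 priors = default_priors())
#' @export
root_model <- function(law = c("negative_exponential", "linear"),
                       branching = c("uniform", "min_separation",
                                     "fixed_spacing"),
                       priors, fixed = list(),
                       name = NULL) {
  law <- match.arg(law)
  branching <- match.arg(branching)
  stopifnot(inherits(priors, "abc_priors"), is.list(fixed))
  have <- c(names(priors), names(fixed))
  if (anyDuplicated(have))
    stop("parameter both free and fixed: ",
         have[duplicated(have)][1L], call. = FALSE)
  need <- switch(branching,
                 uniform = "b",
                 min_separation = c("b", "delta"),
                 fixed_spacing = "d")
  need <- c(need, "g")
  if (law == "negative_exponential") need <- c(need, "l_max")
  miss <- setdiff(need, have)
  if (length(miss))
    stop("model lacks parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(name)) name <- paste(law, branching, sep = "/")
  structure(list(name = name, law = law, branching = branching,
                 priors = priors, fixed = fixed),
            class = "root_model")
}

#' @export
print.root_model <- function(x, ...) {
  cat(sprintf("Root model '%s': %s growth, %s branching\n", x$name, x$law,
              x$branching))
  cat("  free  :", paste(names(x$priors), collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed :", paste(sprintf("%s = %g", names(x$fixed),
                                   unlist(x$fixed)), collapse = ", "), "\n")
  invisible(x)
}

# Assemble full parameter set and simulate one plant's summary matrix at the
# given observation days.
model_simulate_summary <- function(model, theta, days) {
  p <- c(as.list(theta), model$fixed)
  # bare lists, not the validating constructors: this is the ABC hot path
  branching <- switch(model$branching,
    uniform = list(kind = "uniform", b = p$b),
    min_separation = list(kind = "min_separation", b = p$b, delta = p$delta),
    fixed_spacing = list(kind = "fixed_spacing", d = p$d,
                         b_max = p$b_max %||% Inf, spacing_cv = 0))
  simulate_summary_matrix(g = p$g,
                          l_max = p$l_max %||% Inf,
                          alpha = p$alpha %||% 0,
                          law = model$law, branching = branching,
                          days = days)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
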