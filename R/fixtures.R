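#' Specify a synthetic root-system dataset
#'
#' Describes a population of simulated plants sharing mean generative
#' parameters, with per-plant Gaussian multiplicative variability on the
#' growth rates (`growth_cv`) and, under fixed-spacing branching, on each
#' inter-lateral gap (`spacing_cv`, both truncated to stay positive).
#' [arabidopsis_fixture_spec()] and [lupinus_fixture_spec()] are presets
#' emulating published root-simulator parametrizations of *Arabidopsis
#' thaliana* (primary rate 0.49 cm/day, lateral rate 0.08 cm/day,
#' inter-lateral distance 0.2 cm, CVs 0.1 and 0.45) and *Lupinus
#' angustifolius* (initial primary rate 1 cm/day, laterals 0.2 cm/day,
#' inter-root distance 0.9 cm), both under the negative-exponential law and
#' observed at a 15-day horizon.
#'
#' @param species label stored with the dataset.
#' @param law growth law for all roots.
#' @param g mean primary elongation rate, cm/day.
#' @param l_max asymptotic length scale, cm.
#' @param lateral_rate mean lateral elongation rate, cm/day (defines
#'   `alpha = lateral_rate / g`).
#' @param branching a [branching model][branching_models]; its `spacing_cv`
#'   field is overridden by `spacing_cv` below for fixed spacing.
#' @param growth_cv coefficient of variation of per-plant rates (`>= 0`).
#' @param spacing_cv coefficient of variation of inter-lateral gaps
#'   (fixed-spacing branching only).
#' @param n_plants number of plants (`>= 1`).
#' @param days observation days (strictly increasing, `> 0`).
#' @return an object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(species, law = c("negative_exponential", "linear"),
                         g, l_max = Inf, lateral_rate = 0, branching,
                         growth_cv = 0, spacing_cv = 0, n_plants = 1L,
                         days = 15) {
  law <- match.arg(law)
  stopifnot(inherits(branching, "branching_model"), g > 0, lateral_rate >= 0,
            growth_cv >= 0, spacing_cv >= 0, n_plants >= 1L,
            all(days > 0), !is.unsorted(days, strictly = TRUE))
  if (lateral_rate > g)
    stop("'lateral_rate' must not exceed 'g' (alpha <= 1)", call. = FALSE)
  structure(list(species = species, law = law, g = g, l_max = l_max,
                 lateral_rate = lateral_rate, branching = branching,
                 growth_cv = growth_cv, spacing_cv = spacing_cv,
                 n_plants = as.integer(n_plants), days = days),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
arabidopsis_fixture_spec <- function(n_plants = 1L, days = 15) {
  fixture_spec("arabidopsis-crootbox", "negative_exponential",
               g = 0.49, l_max = 20, lateral_rate = 0.08,
               branching = fixed_spacing_branching(d = 0.2, b_max = 50),
               growth_cv = 0.1, spacing_cv = 0.45,
               n_plants = n_plants, days = days)
}

#' @rdname fixture_spec
#' @export
lupinus_fixture_spec <- function(n_plants = 1L, days = 15) {
  fixture_spec("lupinus-rootbox", "negative_exponential",
               g = 1, l_max = 30, lateral_rate = 0.2,
               branching = fixed_spacing_branching(d = 0.9, b_max = 50),
               growth_cv = 0.1, spacing_cv = 0.45,
               n_plants = n_plants, days = days)
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(
    "Fixture spec '%s': %s law, g = %g, lateral rate = %g, %s branching\n",
    x$species, x$law, x$g, x$lateral_rate, x$branching$kind))
  cat(sprintf("  %d plant(s), days %s, growth CV %g, spacing CV %g\n",
              x$n_plants, paste(x$days, collapse = ", "), x$growth_cv,
              x$spacing_cv))
  invisible(x)
}

# multiplicative Gaussian factor truncated at zero
trunc_factor <- function(cv) {
  if (cv == 0) return(1)
  repeat {
    f <- 1 + cv * stats::rnorm(1L)
    if (f > 0) return(f)
  }
}

#' Generate a synthetic observation set with known ground truth
#'
#' Simulates `spec$n_plants` plants: each plant's primary and lateral rates
#' are the spec means times independent truncated Gaussian factors of
#' coefficient of variation `growth_cv`, and (for fixed spacing) each
#' inter-lateral gap is jittered with coefficient of variation `spacing_cv`.
#' Summary statistics are recorded at the spec's observation days. The
#' generative parameters, both the means and every plant's realised rates,
#' are returned alongside the data so that recovery can be judged against
#' them.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer seed; the dataset is deterministic given `(spec, seed)`.
#' @return an object of class `"root_fixture"`: list with `observations` (a
#'   summary table) and `truth` (spec parameters plus per-plant realised
#'   rates and the seed).
#' @export
make_fixture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  branching <- spec$branching
  if (branching$kind == "fixed_spacing") branching$spacing_cv <- spec$spacing_cv
  obs <- vector("list", spec$n_plants)
  per_plant <- data.frame(plant_id = sprintf("p%d", seq_len(spec$n_plants)),
                          g = NA_real_, lateral_rate = NA_real_)
  for (i in seq_len(spec$n_plants)) {
    g_i <- spec$g * trunc_factor(spec$growth_cv)
    lat_i <- spec$lateral_rate * trunc_factor(spec$growth_cv)
    alpha_i <- min(lat_i / g_i, 1)
    per_plant$g[i] <- g_i
    per_plant$lateral_rate[i] <- alpha_i * g_i
    sm <- simulate_summary_matrix(g = g_i, l_max = spec$l_max,
                                  alpha = alpha_i, law = spec$law,
                                  branching = branching, days = spec$days)
    obs[[i]] <- data.frame(plant_id = per_plant$plant_id[i], day = spec$days,
                           sm)
  }
  observations <- as_root_observations(do.call(rbind, obs))
  truth <- list(species = spec$species, law = spec$law, g = spec$g,
                l_max = spec$l_max, lateral_rate = spec$lateral_rate,
                alpha = spec$lateral_rate / spec$g,
                branching = unclass(spec$branching),
                growth_cv = spec$growth_cv, spacing_cv = spec$spacing_cv,
                days = spec$days, seed = seed, per_plant = per_plant)
  structure(list(observations = observations, truth = truth),
            class = "root_fixture")
}

#' @export
print.root_fixture <- function(x, ...) {
  cat(sprintf("Synthetic root dataset '%s': %d plant(s) x %d day(s), seed %s\n",
              x$truth$species, nrow(x$truth$per_plant),
              length(x$truth$days), format(x$truth$seed)))
  invisible(x)
}

#' Generate a pair of phenotypes differing in primary growth rate
#'
#' Produces two synthetic datasets from the same spec, the second with the
#' mean primary rate (and lateral rate, preserving `alpha`) scaled down by
#' `reduced_g_factor` -- a wild-type versus reduced-growth-mutant pair for
#' testing that inference separates the phenotypes in parameter space.
#'
#' @param spec a [fixture_spec()] for the wild type.
#' @param reduced_g_factor factor in (0, 1] applied to the mutant's rates.
#' @param seed integer seed (the two datasets use `seed` and `seed + 1`).
#' @return list with elements `wild_type` and `mutant`, each a
#'   `"root_fixture"`.
#' @export
make_phenotype_pair <- function(spec, reduced_g_factor = 0.5, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"),
            reduced_g_factor > 0, reduced_g_factor <= 1)
  mutant_spec <- spec
  mutant_spec$g <- spec$g * reduced_g_factor
  mutant_spec$lateral_rate <- spec$lateral_rate * reduced_g_factor
  mutant_spec$species <- paste0(spec$species, "-reduced")
  list(wild_type = make_fixture(spec, seed = seed),
       mutant = make_fixture(mutant_spec, seed = seed + 1L))
}
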