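#' Read and write longitudinal root summary tables
#'
#' The on-disk format is a plain CSV (UTF-8, '.' decimal separator) with the
#' exact header `plant_id,day,n_branches,primary_length_cm,
#' mean_lateral_length_cm`. Reading validates the table (see
#' [as_root_observations()]); invalid rows are rejected with their row
#' number, never coerced.
#'
#' @param path file path.
#' @return `read_summary_csv()` returns a validated `"root_observations"`
#'   data frame.
#' @examples
#' obs <- read_summary_csv(system.file("extdata",
#'   "synthetic_arabidopsis_summary.csv", package = "rootabc"))
#' head(obs)
#' @export
read_summary_csv <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (!identical(header, summary_columns))
    stop("bad header: expected columns ",
         paste(summary_columns, collapse = ", "), call. = FALSE)
  x <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric",
                                            "numeric", "numeric"))
  as_root_observations(x)
}

#' @rdname read_summary_csv
#' @param observations a summary table.
#' @export
write_summary_csv <- function(observations, path) {
  obs <- as_root_observations(observations)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

rsml_unit_to_cm <- function(unit) {
  switch(tolower(unit),
         cm = 1, mm = 0.1, m = 100, um = 1e-4, micrometer = 1e-4,
         inch = 2.54, pixel = NA_real_,
         NA_real_)
}

polyline_coords <- function(root_node) {
  pts <- xml2::xml_find_all(root_node, "./geometry/polyline/point")
  if (!length(pts)) stop("RSML root without polyline geometry", call. = FALSE)
  cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
        y = as.numeric(xml2::xml_attr(pts, "y")))
}

polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# arc length along the polyline at each vertex
polyline_arclength <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
}

#' Read a traced root system from an RSML file
#'
#' Parses a Root System Markup Language document (as written by root-tracing
#' software) into one snapshot per plant. The topmost (first) root of each
#' plant is taken as the primary; its child roots are the lateral branches,
#' with lengths summed over their polyline segments and positions given by
#' the primary arc length at the vertex nearest the lateral's first point.
#' Deeper-order roots are ignored with a warning. Coordinates are converted
#' to cm using the document's resolution and unit metadata; if these are
#' absent or in pixels, coordinates are assumed to be cm and a warning is
#' issued.
#'
#' @param path path to an RSML (XML) file.
#' @param observation_day day recorded in the returned snapshots.
#' @return list of `"root_snapshot"` objects, one per plant (branch `t_init`
#'   is unknown from a static tracing and set to `NA`).
#' @examples
#' snaps <- read_rsml(system.file("extdata", "synthetic_plant.rsml",
#'                                package = "rootabc"), observation_day = 10)
#' summarize_snapshot(snaps[[1]])
#' @export
read_rsml <- function(path, observation_day = NA_real_) {
  doc <- xml2::read_xml(path)
  res <- xml2::xml_find_first(doc, ".//metadata/resolution")
  unit <- xml2::xml_find_first(doc, ".//metadata/unit")
  scale <- NA_real_
  if (!inherits(res, "xml_missing") && !inherits(unit, "xml_missing")) {
    per_unit <- as.numeric(xml2::xml_text(res))
    to_cm <- rsml_unit_to_cm(xml2::xml_text(unit))
    if (is.finite(per_unit) && per_unit > 0 && !is.na(to_cm))
      scale <- to_cm / per_unit
  }
  if (is.na(scale)) {
    warning("RSML resolution/unit metadata absent or in pixels; ",
            "assuming coordinates are cm")
    scale <- 1
  }
  plants <- xml2::xml_find_all(doc, ".//scene/plant")
  if (!length(plants)) stop("RSML document contains no plants", call. = FALSE)
  lapply(plants, function(plant) {
    tops <- xml2::xml_find_all(plant, "./root")
    if (!length(tops)) stop("RSML plant without roots", call. = FALSE)
    primary <- tops[[1L]]
    if (length(tops) > 1L)
      warning("plant has ", length(tops),
              " top-level roots; using the first as primary")
    pc <- polyline_coords(primary) * scale
    arc <- polyline_arclength(pc)
    laterals <- xml2::xml_find_all(primary, "./root")
    if (length(xml2::xml_find_all(primary, "./root/root")))
      warning("ignoring roots of order > 1")
    br <- data.frame(position = numeric(), t_init = numeric(),
                     length = numeric())
    if (length(laterals)) {
      br <- do.call(rbind, lapply(laterals, function(lat) {
        lc <- polyline_coords(lat) * scale
        d2 <- colSums((t(pc) - lc[1L, ])^2)
        data.frame(position = arc[which.min(d2)], t_init = NA_real_,
                   length = polyline_length(lc))
      }))
      br <- br[order(br$position), ]
      rownames(br) <- NULL
    }
    structure(list(time = observation_day,
                   primary_length = polyline_length(pc), branches = br),
              class = "root_snapshot")
  })
}

#' Write ABC SMC results to disk
#'
#' Writes three files into `out_dir`: `particles.csv` (population, model,
#' parameter columns, weight, distance), `model_probabilities.csv`
#' (population, model, probability) and `metadata.json` (seed, schedule,
#' priors, fixed parameters, acceptance attempts, particle count). Output is
#' stable for a fixed fit.
#'
#' @param object a `"root_abc"` fit.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(object, out_dir) {
  stopifnot(inherits(object, "root_abc"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  particles <- do.call(rbind, object$populations)
  p_path <- file.path(out_dir, "particles.csv")
  utils::write.csv(particles, p_path, row.names = FALSE, quote = FALSE)
  mp <- object$model_probabilities
  mp_df <- data.frame(population = rep(seq_len(nrow(mp)), ncol(mp)),
                      model = rep(colnames(mp), each = nrow(mp)),
                      probability = as.vector(mp))
  m_path <- file.path(out_dir, "model_probabilities.csv")
  utils::write.csv(mp_df, m_path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = object$seed, schedule = object$schedule,
               n_particles = object$n_particles,
               kernel_scale = object$kernel_scale,
               feature_weights = object$weights,
               attempts = object$attempts,
               model_prior = as.list(object$model_prior),
               models = lapply(object$models, function(m)
                 list(law = m$law, branching = m$branching,
                      priors = lapply(m$priors, identity), fixed = m$fixed)))
  j_path <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, j_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(particles = p_path, model_probabilities = m_path,
              metadata = j_path))
}

#' Write or read a synthetic fixture (data plus ground truth)
#'
#' Stores the observation table as `observations.csv` and the generative
#' ground truth as `truth.json`; [read_fixture()] restores both.
#'
#' @param fixture a `"root_fixture"` from [make_fixture()].
#' @param dir directory (created if needed).
#' @return `read_fixture()` returns a `"root_fixture"`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "root_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_csv(fixture$observations, file.path(dir, "observations.csv"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  observations <- read_summary_csv(file.path(dir, "observations.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$per_plant <- as.data.frame(truth$per_plant)
  structure(list(observations = observations, truth = truth),
            class = "root_fixture")
}

#' Read a structured inference configuration
#'
#' Reads a YAML configuration describing one or more candidate models, the
#' tolerance schedule and sampler settings, and assembles the pieces used by
#' [abc_smc()]. Recognised top-level keys: `models` (list; each with `law`,
#' `branching`, `priors` as `{name: [lower, upper]}`, optional `fixed` and
#' `name`), `final_epsilon` or `schedule`, `n_particles`, `kernel_scale`,
#' `feature_weights`, `seed`.
#'
#' @param path path to a YAML file.
#' @return list with elements `models` (list of [root_model()]), `schedule`,
#'   `n_particles`, `kernel_scale`, `weights`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models)) stop("config lacks 'models'", call. = FALSE)
  models <- lapply(cfg$models, function(m) {
    pr <- do.call(abc_priors, lapply(m$priors, as.numeric))
    root_model(law = m$law %||% "negative_exponential",
               branching = m$branching %||% "uniform",
               priors = pr, fixed = m$fixed %||% list(),
               name = m$name %||% NULL)
  })
  schedule <- if (!is.null(cfg$schedule)) as.numeric(cfg$schedule)
              else if (!is.null(cfg$final_epsilon))
                tolerance_schedule(cfg$final_epsilon)
              else stop("config needs 'schedule' or 'final_epsilon'",
                        call. = FALSE)
  list(models = models, schedule = schedule,
       n_particles = as.integer(cfg$n_particles %||% 1000L),
       kernel_scale = cfg$kernel_scale %||% 0.1,
       weights = as.numeric(cfg$feature_weights %||% c(1, 1, 1)),
       seed = cfg$seed %||% NULL)
}
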