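#' Summary statistics of a root structure
#'
#' Reduces a root system snapshot to the triple used throughout the
#' inference: the branch count `B`, primary root length `L` (cm) and mean
#' lateral root length `l_hat` (cm, 0 when there are no branches). Every
#' branch point counts towards `B`, including just-initiated zero-length
#' laterals.
#'
#' @param snapshot a `"root_snapshot"` (from [simulate_root_system()] or
#'   [read_rsml()]).
#' @return named numeric vector `c(B, L, l_hat)`.
#' @export
summarize_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "root_snapshot"))
  n <- nrow(snapshot$branches)
  c(B = n,
    L = snapshot$primary_length,
    l_hat = if (n) mean(snapshot$branches$length) else 0)
}

#' Longitudinal summary table of a simulated root system
#'
#' @param system a `"root_system"`.
#' @param plant_id identifier recorded in the `plant_id` column.
#' @return a summary data frame with columns `plant_id`, `day`, `n_branches`,
#'   `primary_length_cm`, `mean_lateral_length_cm` (one row per snapshot).
#' @export
summarize_system <- function(system, plant_id = "p1") {
  stopifnot(inherits(system, "root_system"))
  rows <- t(vapply(system$snapshots, summarize_snapshot, numeric(3L)))
  data.frame(plant_id = plant_id,
             day = vapply(system$snapshots, `[[`, numeric(1L), "time"),
             n_branches = as.integer(rows[, "B"]),
             primary_length_cm = rows[, "L"],
             mean_lateral_length_cm = rows[, "l_hat"])
}

summary_columns <- c("plant_id", "day", "n_branches", "primary_length_cm",
                     "mean_lateral_length_cm")

#' Validate a longitudinal observation table
#'
#' An observation set is a data frame with columns `plant_id`, `day`,
#' `n_branches`, `primary_length_cm` and `mean_lateral_length_cm`, one row
#' per plant and observation day. Days must be strictly increasing within
#' each plant, counts must be non-negative integers and lengths non-negative.
#'
#' @param x a data frame.
#' @return `x`, invisibly validated, with class `"root_observations"`.
#' @export
as_root_observations <- function(x) {
  if (!is.data.frame(x)) stop("observations must be a data frame", call. = FALSE)
  missing_cols <- setdiff(summary_columns, names(x))
  if (length(missing_cols))
    stop("missing observation columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- x[summary_columns]
  if (!nrow(x)) stop("no plants: observation table is empty", call. = FALSE)
  bad <- which(x$n_branches < 0 | x$n_branches != round(x$n_branches))
  if (length(bad))
    stop("row ", bad[1L], ": n_branches must be a non-negative integer",
         call. = FALSE)
  bad <- which(x$primary_length_cm < 0 | x$mean_lateral_length_cm < 0 |
                 x$day <= 0)
  if (length(bad))
    stop("row ", bad[1L], ": days must be positive and lengths non-negative",
         call. = FALSE)
  for (id in unique(x$plant_id)) {
    d <- x$day[x$plant_id == id]
    if (anyDuplicated(d))
      stop("duplicate observation day for plant '", id, "'", call. = FALSE)
    if (is.unsorted(d, strictly = TRUE))
      stop("observation days not strictly increasing for plant '", id, "'",
           call. = FALSE)
  }
  class(x) <- c("root_observations", "data.frame")
  x
}

#' Distance between two summary-statistic triples
#'
#' Scaled Euclidean distance between two `(B, L, l_hat)` triples:
#' \deqn{\rho(d_1, d_2) = \sqrt{\tfrac13\left[w_B(B_1-B_2)^2 +
#'   w_L(L_1-L_2)^2 + w_l(\hat l_1-\hat l_2)^2\right]}}
#' With the default unit weights all three features are compared on their
#' natural cm / count scales.
#'
#' @param d1,d2 numeric triples `(B, L, l_hat)`.
#' @param weights optional non-negative per-feature weights (length 3).
#' @return non-negative scalar distance.
#' @examples
#' pair_distance(c(3, 2, 1), c(0, 0, 0))  # sqrt(14/3)
#' @export
pair_distance <- function(d1, d2, weights = c(1, 1, 1)) {
  stopifnot(length(d1) == 3L, length(d2) == 3L, length(weights) == 3L,
            all(weights >= 0))
  sqrt(sum(weights * (d1 - d2)^2) / 3)
}

#' Distance between an observed and a simulated dataset
#'
#' Sums [pair_distance()] over every matched (plant, day) pair of two summary
#' tables. The simulated table must contain exactly the plants and
#' observation days of the observed table; each observed plant is compared
#' with its own simulated counterpart recorded at the same days.
#'
#' @param observed,simulated summary data frames (see [as_root_observations()]).
#' @param weights per-feature weights passed to [pair_distance()].
#' @return total distance (non-negative scalar).
#' @export
dataset_distance <- function(observed, simulated, weights = c(1, 1, 1)) {
  ko <- paste(observed$plant_id, observed$day)
  ks <- paste(simulated$plant_id, simulated$day)
  idx <- match(ko, ks)
  if (anyNA(idx))
    stop("simulated set lacks (plant, day) pair: ", ko[which(is.na(idx))[1L]],
         call. = FALSE)
  if (length(ks) != length(ko))
    stop("simulated set has ", length(ks), " rows but observed has ",
         length(ko), call. = FALSE)
  feats <- c("n_branches", "primary_length_cm", "mean_lateral_length_cm")
  om <- as.matrix(observed[feats])
  sm <- as.matrix(simulated[feats])[idx, , drop = FALSE]
  dd <- (om - sm)^2
  sum(sqrt((dd %*% weights) / 3))
}

# Distance between an observation matrix and a simulated summary matrix with
# identical row order; hot path of the ABC loops.
distance_matrix_rows <- function(om, sm, weights = c(1, 1, 1)) {
  dd <- (om - sm)^2
  sum(sqrt((dd %*% weights) / 3))
}
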