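#' Run-day median normalisation of a non-targeted panel
#'
#' Divides each observed intensity by the median of the observed values of
#' that metabolite among samples acquired on the same run day, removing
#' between-day batch drift. After normalisation every (metabolite, run-day)
#' group with at least one observation has median 1.
#'
#' @param panel a `non_targeted` [metabolite_panel()].
#' @return The normalised panel, with step `"median_normalize"` recorded.
#' @export
run_day_median_normalize <- function(panel) {
  check_state(panel, "run_day_median_normalize", platform = "non_targeted",
              forbid = c("median_normalize", "filter_missingness",
                         "impute_run_day_minimum", "inverse_normal"))
  v <- panel$values
  for (day in unique(panel$run_day)) {
    rows <- panel$run_day == day
    med <- apply(v[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    all_missing <- is.na(med)  # whole day missing for a metabolite
    if (any(all_missing))
      warning(sprintf("run day %s: all values missing for %d metabolite(s); left missing",
                      day, sum(all_missing)))
    med[all_missing] <- 1  # no-op divisor; cells stay NA anyway
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, med, "/")
  }
  panel$values <- v
  record_step(panel, "median_normalize")
}

#' Exclude metabolites with too many missing values
#'
#' Removes metabolites whose missing fraction is strictly greater than
#' `max_missing_frac` (a metabolite missing exactly that fraction is kept).
#'
#' @param panel a [metabolite_panel()].
#' @param max_missing_frac highest tolerated missing fraction; default 0.20.
#' @return List with `panel` (filtered, step `"filter_missingness"` recorded)
#'   and `excluded` (character vector of removed metabolite ids, in panel
#'   order).
#' @export
filter_missingness <- function(panel, max_missing_frac = 0.20) {
  check_state(panel, "filter_missingness",
              forbid = c("filter_missingness", "impute_run_day_minimum",
                         "inverse_normal"))
  miss_frac <- colMeans(is.na(panel$values))
  drop <- miss_frac > max_missing_frac
  excluded <- colnames(panel$values)[drop]
  panel$values <- panel$values[, !drop, drop = FALSE]
  if (!is.null(panel$annotation))
    panel$annotation <- panel$annotation[!panel$annotation$metabolite %in% excluded, ,
                                         drop = FALSE]
  panel <- record_step(panel, "filter_missingness")
  list(panel = panel, excluded = excluded)
}

#' Impute missing values with the run-day minimum
#'
#' Each missing cell is set to the minimum observed value of that metabolite
#' on that sample's run day; when the metabolite is entirely missing on that
#' day, the global minimum of the metabolite is used instead. Intended for
#' left-censored (low-abundance) missingness after [filter_missingness()].
#'
#' @param panel a [metabolite_panel()] that has passed the missingness filter.
#' @return Fully observed panel, step `"impute_run_day_minimum"` recorded.
#' @export
impute_run_day_minimum <- function(panel) {
  check_state(panel, "impute_run_day_minimum",
              require = "filter_missingness",
              forbid = c("impute_run_day_minimum", "inverse_normal"))
  v <- panel$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop(sprintf("metabolite(s) with no observed values should have been filtered: %s",
                 paste(colnames(v)[n_obs == 0], collapse = ", ")))
  global_min <- apply(v, 2, min, na.rm = TRUE)
  for (day in unique(panel$run_day)) {
    rows <- which(panel$run_day == day)
    block <- v[rows, , drop = FALSE]
    day_min <- suppressWarnings(apply(block, 2, min, na.rm = TRUE))
    day_min[!is.finite(day_min)] <- global_min[!is.finite(day_min)]
    na_idx <- which(is.na(block), arr.ind = TRUE)
    if (nrow(na_idx)) block[na_idx] <- day_min[na_idx[, 2]]
    v[rows, ] <- block
  }
  panel$values <- v
  record_step(panel, "impute_run_day_minimum")
}

#' Rank-based inverse normal transformation (Blom)
#'
#' Maps a numeric vector onto standard-normal quantiles through its ranks,
#' using the Blom offset: `qnorm((r - 3/8) / (n + 1/4))` with ties given
#' their average rank. The result depends on the input only through rank
#' order.
#'
#' @param values numeric vector, length >= 2, at least two distinct values.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2)
    stop("inverse_normal_transform: need at least 2 values")
  if (anyNA(values))
    stop("inverse_normal_transform: missing values must be imputed first")
  if (length(unique(values)) < 2)
    stop("inverse_normal_transform: constant vector, transform undefined")
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.375) / (length(values) + 0.25))
}

#' Apply the inverse normal transformation to every metabolite of a panel
#'
#' @param panel a fully observed [metabolite_panel()] (after imputation for
#'   the non-targeted chain).
#' @return Panel with each metabolite column transformed, step
#'   `"inverse_normal"` recorded.
#' @export
inverse_normalize_panel <- function(panel) {
  check_state(panel, "inverse_normalize_panel",
              require = if (panel$platform == "non_targeted")
                c("filter_missingness", "impute_run_day_minimum") else character(),
              forbid = "inverse_normal")
  panel$values <- apply(panel$values, 2, inverse_normal_transform)
  rownames(panel$values) <- subject_ids(panel)
  record_step(panel, "inverse_normal")
}

#' Natural-log transform a targeted panel
#'
#' Targeted concentrations are right-skewed; analysis is done on the log
#' scale. All observed values must be strictly positive.
#'
#' @param panel a `targeted` [metabolite_panel()].
#' @return Log-transformed panel, step `"log_transform"` recorded.
#' @export
log_transform_targeted <- function(panel) {
  check_state(panel, "log_transform_targeted", platform = "targeted",
              forbid = "log_transform")
  bad <- which(panel$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive concentration at subject %s, metabolite %s",
                 rownames(panel$values)[bad[1, 1]],
                 colnames(panel$values)[bad[1, 2]]))
  }
  panel$values <- log(panel$values)
  record_step(panel, "log_transform")
}

#' Drop metabolites measured on both platforms from the targeted panel
#'
#' When the same compound is quantified by both the non-targeted and the
#' targeted assay, it is analysed on the non-targeted platform only and
#' removed from the targeted panel here.
#'
#' @param panel a `targeted` [metabolite_panel()].
#' @param overlap_ids metabolite ids to remove. Ids not present in the panel
#'   trigger a warning naming them (not an error): the overlap list may be
#'   broader than a given assay run.
#' @return Panel without the listed metabolites.
#' @export
drop_overlapping <- function(panel, overlap_ids) {
  check_state(panel, "drop_overlapping", platform = "targeted")
  overlap_ids <- as.character(overlap_ids)
  absent <- setdiff(overlap_ids, colnames(panel$values))
  if (length(absent))
    warning(sprintf("overlap id(s) not in panel: %s", paste(absent, collapse = ", ")))
  keep <- !colnames(panel$values) %in% overlap_ids
  panel$values <- panel$values[, keep, drop = FALSE]
  if (!is.null(panel$annotation))
    panel$annotation <- panel$annotation[panel$annotation$metabolite %in%
                                           colnames(panel$values), , drop = FALSE]
  if (!"drop_overlapping" %in% panel$steps)
    panel <- record_step(panel, "drop_overlapping")
  panel
}

#' Full preprocessing chain for a non-targeted panel
#'
#' Run-day median normalisation, missingness filter (strict `>` rule),
#' run-day-minimum imputation, then per-metabolite inverse normal
#' transformation — in that order.
#'
#' @param panel raw `non_targeted` [metabolite_panel()].
#' @param max_missing_frac passed to [filter_missingness()]; default 0.20.
#' @return List with `panel` (processed) and `excluded` (metabolite ids
#'   removed by the missingness filter).
#' @export
preprocess_nontargeted <- function(panel, max_missing_frac = 0.20) {
  panel <- run_day_median_normalize(panel)
  flt <- filter_missingness(panel, max_missing_frac)
  panel <- impute_run_day_minimum(flt$panel)
  panel <- inverse_normalize_panel(panel)
  list(panel = panel, excluded = flt$excluded)
}

#' Full preprocessing chain for a targeted panel
#'
#' Log transform, then removal of metabolites overlapping the non-targeted
#' platform.
#'
#' @param panel raw `targeted` [metabolite_panel()].
#' @param overlap_ids ids to pass to [drop_overlapping()].
#' @return Processed panel.
#' @export
preprocess_targeted <- function(panel, overlap_ids = character()) {
  panel <- log_transform_targeted(panel)
  drop_overlapping(panel, overlap_ids)
}
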