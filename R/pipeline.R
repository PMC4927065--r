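#' Run the full association pipeline on a twin cohort
#'
#' End-to-end orchestration of the co-twin control scan: builds the
#' energy-adjusted food-group matrix from the FFQ, preprocesses the
#' non-targeted (median-normalise, filter, impute, inverse-normal) and
#' targeted (log, drop platform overlaps) panels, runs the discovery scan on
#' each platform with a single Bonferroni denominator spanning all tested
#' (food group, metabolite) pairs on both platforms, replicates
#' discovery-significant associations in the MZ-discordant pairs, and
#' meta-analyses the two stages by inverse-variance fixed-effect weighting.
#' Reported associations are the meta records; they are flagged
#' `significant` at the scan threshold and `replicated` per the stage-two
#' criteria.
#'
#' @param data list with `cohort`, and either `foods` (subjects x food
#'   groups matrix, already energy-adjusted) or `ffq` plus `food_map`;
#'   optional `panel_nt`, `panel_t` (raw [metabolite_panel()]s), `genotypes`
#'   and `snp_food_map` — the output of [simulate_cohort()] is accepted
#'   directly.
#' @param alpha family-wise error level for the scan; default 0.05.
#' @param sd_multiplier MZ-discordance margin in intake SDs; default 1.
#' @param replication_alpha replication significance level; default 0.05.
#' @param max_missing_frac missingness filter cut-off; default 0.20.
#' @param overlap_ids targeted metabolite ids overlapping the non-targeted
#'   platform, removed before analysis.
#' @param n_tests multiplicity denominator override (e.g. a fixed
#'   food-groups-times-metabolites product); default: all tested pairs
#'   across both platforms.
#' @param adjust_order energy-adjustment order for the diet chain.
#' @param run_genotype_scan fit the SNP follow-up scan when genotypes are
#'   present; default `TRUE`.
#' @param outdir optional directory: results tables are written as TSV plus
#'   a JSON provenance block.
#' @return An object of class `results_bundle`: `discovery`, `replication`,
#'   `meta` tables, `partitions`, `thresholds`, `counts`, `snp` (or NULL),
#'   `excluded_nt`, and `provenance`.
#' @export
run_pipeline <- function(data, alpha = 0.05, sd_multiplier = 1,
                         replication_alpha = 0.05, max_missing_frac = 0.20,
                         overlap_ids = character(), n_tests = NULL,
                         adjust_order = c("group", "item"),
                         run_genotype_scan = TRUE, outdir = NULL) {
  adjust_order <- match.arg(adjust_order)
  cohort <- data$cohort
  foods <- if (!is.null(data$foods)) data$foods else
    build_food_group_matrix(data$ffq, data$food_map, adjust_order = adjust_order)

  panels <- list()
  excluded_nt <- character()
  if (!is.null(data$panel_nt)) {
    pre <- preprocess_nontargeted(data$panel_nt, max_missing_frac)
    panels$non_targeted <- pre$panel
    excluded_nt <- pre$excluded
  }
  if (!is.null(data$panel_t))
    panels$targeted <- preprocess_targeted(data$panel_t, overlap_ids)
  if (!length(panels)) stop("no metabolite panel supplied")

  n_metab_total <- sum(vapply(panels, function(p) ncol(p$values), 0L))
  if (is.null(n_tests)) n_tests <- ncol(foods) * n_metab_total
  threshold <- bonferroni_threshold(alpha, n_tests)

  discovery <- list(); replication <- list(); meta <- list()
  partitions <- NULL
  for (pf in names(panels)) {
    scan <- discovery_scan(panels[[pf]], foods, cohort, alpha = alpha,
                           sd_multiplier = sd_multiplier, n_tests = n_tests)
    if (is.null(partitions)) partitions <- scan$partitions
    discovery[[pf]] <- scan$records
    sig <- scan$records[scan$records$significant, , drop = FALSE]
    rep_recs <- replicate_associations(sig, panels[[pf]], foods, cohort,
                                       scan$partitions, replication_alpha)
    replication[[pf]] <- rep_recs
    mrecs <- vector("list", nrow(sig))
    for (i in seq_len(nrow(sig))) {
      r <- rep_recs[i, ]
      if (is.na(r$beta)) next  # not testable in replication: no meta record
      m <- meta_fixed_effect(sig[i, ], r, threshold = threshold,
                             replicated = r$replicated)
      m$platform <- pf
      mrecs[[i]] <- m
    }
    mrecs <- mrecs[!vapply(mrecs, is.null, TRUE)]
    if (length(mrecs)) meta[[pf]] <- do.call(rbind, mrecs)
  }
  discovery <- do.call(rbind, c(discovery, list(make.row.names = FALSE)))
  replication <- do.call(rbind, c(replication, list(make.row.names = FALSE)))
  meta <- if (length(meta))
    do.call(rbind, c(meta, list(make.row.names = FALSE))) else
    data.frame(food_group = character(), metabolite = character(),
               beta = numeric(), se = numeric(), p = numeric(),
               replicated = logical(), significant = logical(),
               platform = character(), stringsAsFactors = FALSE)

  snp <- NULL
  if (run_genotype_scan && !is.null(data$genotypes) &&
      !is.null(data$snp_food_map) && nrow(data$snp_food_map) > 0)
    snp <- snp_scan(data$snp_food_map, data$genotypes, foods, cohort, alpha)

  bundle <- structure(list(
    discovery = discovery, replication = replication, meta = meta,
    partitions = partitions, snp = snp, excluded_nt = excluded_nt,
    panels = lapply(panels, function(p)
      list(platform = p$platform, metabolites = colnames(p$values),
           annotation = p$annotation, steps = p$steps)),
    thresholds = list(alpha = alpha, n_tests = n_tests,
                      bonferroni = threshold,
                      replication_alpha = replication_alpha,
                      snp = if (!is.null(snp)) snp$threshold else NA_real_),
    counts = NULL,
    provenance = list(
      n_subjects = nrow(cohort), n_food_groups = ncol(foods),
      n_metabolites = n_metab_total, sd_multiplier = sd_multiplier,
      adjust_order = adjust_order, max_missing_frac = max_missing_frac,
      package_version = as.character(utils::packageVersion("twinmetab")))
  ), class = "results_bundle")
  bundle$counts <- summarize_counts(bundle)

  if (!is.null(outdir)) write_results_bundle(bundle, outdir)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat(sprintf("  tested pairs: %d (Bonferroni %.3g)\n",
              x$thresholds$n_tests, x$thresholds$bonferroni))
  cat(sprintf("  discovery-significant: %d; replicated+significant meta: %d\n",
              sum(x$discovery$significant, na.rm = TRUE),
              sum(x$meta$significant & x$meta$replicated, na.rm = TRUE)))
  invisible(x)
}
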