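#' Headline counts of a results bundle
#'
#' Counts the reported (meta-analysed, significant and replicated)
#' associations, the distinct food groups and metabolites involved, split by
#' platform and — where panel annotation is available — by structurally
#' identified ("named") versus unknown metabolites. The counts are
#' recomputable from the bundle's tables at any time.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @return Data frame of named counts.
#' @export
summarize_counts <- function(bundle) {
  meta <- bundle$meta
  hits <- meta[!is.na(meta$significant) & meta$significant &
                 !is.na(meta$replicated) & meta$replicated, , drop = FALSE]
  named_map <- do.call(rbind, lapply(bundle$panels, function(p) p$annotation))
  n_named <- if (!is.null(named_map) && nrow(hits)) {
    sum(unique(hits$metabolite) %in% named_map$metabolite[named_map$named])
  } else 0L
  counts <- data.frame(
    quantity = c("n_tested", "n_discovery_significant", "n_replicated",
                 "n_meta_significant", "n_associations",
                 "n_food_groups", "n_metabolites",
                 "n_metabolites_named", "n_metabolites_unknown",
                 "n_associations_non_targeted", "n_associations_targeted"),
    value = c(nrow(bundle$discovery),
              sum(bundle$discovery$significant, na.rm = TRUE),
              sum(bundle$replication$replicated, na.rm = TRUE),
              sum(meta$significant, na.rm = TRUE),
              nrow(hits),
              length(unique(hits$food_group)),
              length(unique(hits$metabolite)),
              n_named,
              length(unique(hits$metabolite)) - n_named,
              sum(hits$platform == "non_targeted"),
              sum(hits$platform == "targeted")),
    stringsAsFactors = FALSE)
  counts
}

#' Format an effect estimate as "beta[SE]"
#'
#' @param beta,se numeric vectors.
#' @param digits decimal places; default 3 (e.g. `0.075[0.009]`).
#' @return Character vector.
#' @export
format_beta_se <- function(beta, se, digits = 3) {
  sprintf(paste0("%.", digits, "f[%.", digits, "f]"), beta, se)
}

#' Format a p-value in scientific notation with 3 significant figures
#'
#' @param p numeric vector of p-values.
#' @return Character vector like `"1.23x10^-8"`.
#' @export
format_p_sci <- function(p) {
  out <- character(length(p))
  for (i in seq_along(p)) {
    if (is.na(p[i])) { out[i] <- NA_character_; next }
    if (p[i] == 0) { out[i] <- "0"; next }  # normal tail underflow
    e <- floor(log10(p[i]))
    m <- signif(p[i] / 10^e, 3)
    if (m >= 10) { m <- m / 10; e <- e + 1 }  # rounding carry (9.99.. -> 10)
    out[i] <- sprintf("%.2fx10^%d", m, e)
  }
  out
}

#' Flat export of the reported associations
#'
#' One row per significant meta-analysed association, with the effect
#' formatted as `beta[SE]` and the p-value in scientific notation — the flat
#' table behind a queryable diet-metabolite lookup.
#'
#' @param bundle a `results_bundle`.
#' @param path optional file path; when given the table is written as TSV
#'   (header always written, even for an empty table).
#' @return The export data frame (invisibly when `path` is given).
#' @export
export_dietmetab <- function(bundle, path = NULL) {
  hits <- bundle$meta[!is.na(bundle$meta$significant) & bundle$meta$significant, ,
                      drop = FALSE]
  out <- data.frame(
    food_group = hits$food_group, metabolite = hits$metabolite,
    platform = hits$platform,
    beta_se = format_beta_se(hits$beta, hits$se),
    p = format_p_sci(hits$p),
    replicated = hits$replicated, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
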