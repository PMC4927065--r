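# Delimited-text I/O. All tables are TSV with a header row; missing values
# are empty fields. Numeric columns are written with 15 significant digits
# so a write/read round trip is lossless at double precision for practical
# purposes.

tsv_write <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- NA
    out
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

tsv_read <- function(path, ...) {
  read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE, ...)
}

#' Write a metabolite panel as TSV with a JSON sidecar
#'
#' The TSV has columns `subject_id`, `run_day`, then one column per
#' metabolite (missing values as empty fields). A `<path>.json` sidecar
#' records the platform, the applied processing steps and the annotation.
#'
#' @param panel a [metabolite_panel()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(subject_id = subject_ids(panel), run_day = panel$run_day,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(panel$values))
  tsv_write(df, path)
  side <- list(platform = panel$platform, steps = panel$steps,
               annotation = panel$annotation)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a metabolite panel written by [write_panel()]
#'
#' @param path TSV path (the `<path>.json` sidecar must sit next to it).
#' @return A [metabolite_panel()].
#' @export
read_panel <- function(path) {
  df <- tsv_read(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(df[, setdiff(names(df), c("subject_id", "run_day")),
                    drop = FALSE])
  rownames(v) <- df$subject_id
  annotation <- side$annotation
  if (!is.null(annotation) && !is.data.frame(annotation))
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  metabolite_panel(v, df$run_day, side$platform,
                   annotation = annotation,
                   steps = as.character(side$steps %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the tables of a simulated cohort to a directory
#'
#' Writes `cohort.tsv`, `ffq.tsv`, `food_map.tsv`, the panels
#' (`panel_nt.tsv`, `panel_t.tsv` plus sidecars), `genotypes.tsv`,
#' `snp_food_map.tsv` — whichever are present.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv_write(sim$cohort, file.path(dir, "cohort.tsv"))
  tsv_write(sim$ffq, file.path(dir, "ffq.tsv"))
  tsv_write(sim$food_map, file.path(dir, "food_map.tsv"))
  if (!is.null(sim$panel_nt)) write_panel(sim$panel_nt, file.path(dir, "panel_nt.tsv"))
  if (!is.null(sim$panel_t)) write_panel(sim$panel_t, file.path(dir, "panel_t.tsv"))
  if (!is.null(sim$genotypes)) {
    g <- data.frame(subject_id = rownames(sim$genotypes),
                    stringsAsFactors = FALSE)
    tsv_write(cbind(g, as.data.frame(sim$genotypes)),
              file.path(dir, "genotypes.tsv"))
  }
  if (!is.null(sim$snp_food_map))
    tsv_write(sim$snp_food_map, file.path(dir, "snp_food_map.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_dir()]
#'
#' @param dir directory path.
#' @return List with the same elements as [simulate_cohort()] output
#'   (without `truth`).
#' @export
read_cohort_dir <- function(dir) {
  out <- list(cohort = tsv_read(file.path(dir, "cohort.tsv")),
              ffq = tsv_read(file.path(dir, "ffq.tsv")),
              food_map = tsv_read(file.path(dir, "food_map.tsv")))
  pnt <- file.path(dir, "panel_nt.tsv")
  if (file.exists(pnt)) out$panel_nt <- read_panel(pnt)
  pt <- file.path(dir, "panel_t.tsv")
  if (file.exists(pt)) out$panel_t <- read_panel(pt)
  gt <- file.path(dir, "genotypes.tsv")
  if (file.exists(gt)) {
    g <- tsv_read(gt)
    m <- as.matrix(g[, -1, drop = FALSE])
    rownames(m) <- g$subject_id
    out$genotypes <- m
  }
  sf <- file.path(dir, "snp_food_map.tsv")
  if (file.exists(sf)) out$snp_food_map <- tsv_read(sf)
  out
}

#' Write a results bundle to a directory
#'
#' Association tables (`discovery.tsv`, `replication.tsv`, `meta.tsv`,
#' `snp.tsv`), the flat export (`dietmetab.tsv`), the count summary
#' (`counts.tsv`) and a JSON provenance block (`provenance.json`, holding
#' thresholds, counts and configuration).
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv_write(bundle$discovery, file.path(dir, "discovery.tsv"))
  tsv_write(bundle$replication, file.path(dir, "replication.tsv"))
  tsv_write(bundle$meta, file.path(dir, "meta.tsv"))
  if (!is.null(bundle$snp))
    tsv_write(bundle$snp$records, file.path(dir, "snp.tsv"))
  tsv_write(bundle$counts, file.path(dir, "counts.tsv"))
  export_dietmetab(bundle, file.path(dir, "dietmetab.tsv"))
  jsonlite::write_json(
    list(thresholds = bundle$thresholds, provenance = bundle$provenance,
         excluded_nt = bundle$excluded_nt),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
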