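#' Construct a metabolite panel
#'
#' A metabolite panel holds a subjects-by-metabolites value matrix together
#' with per-sample run-day labels, the platform it was measured on, and the
#' ordered list of processing steps already applied to it. Missing
#' measurements are `NA` cells of the value matrix.
#'
#' @param values numeric matrix, subjects in rows, metabolites in columns.
#'   Row names are subject ids, column names metabolite ids (both required).
#' @param run_day character or factor of length `nrow(values)`: the
#'   acquisition day of each sample.
#' @param platform `"non_targeted"` (relative intensities) or `"targeted"`
#'   (absolute concentrations, mM).
#' @param annotation optional data frame with columns `metabolite` and
#'   `named` (logical: structurally identified vs unknown compound).
#' @param steps character vector of processing steps already applied;
#'   normally left empty for raw data.
#'
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(values, run_day, platform = c("non_targeted", "targeted"),
                             annotation = NULL, steps = character()) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have subject ids as row names and metabolite ids as column names")
  run_day <- as.character(run_day)
  if (length(run_day) != nrow(values))
    stop("`run_day` must have one label per sample (row of `values`)")
  if (!is.null(annotation)) {
    if (!all(c("metabolite", "named") %in% names(annotation)))
      stop("`annotation` needs columns `metabolite` and `named`")
  }
  structure(
    list(values = values, run_day = run_day, platform = platform,
         annotation = annotation, steps = steps),
    class = "metabolite_panel"
  )
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("<metabolite_panel> %s: %d subjects x %d metabolites, %d run day(s)\n",
              x$platform, nrow(x$values), ncol(x$values),
              length(unique(x$run_day))))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.1f%%  steps: %s\n", 100 * miss,
              if (length(x$steps)) paste(x$steps, collapse = " -> ") else "<raw>"))
  invisible(x)
}

#' @export
dim.metabolite_panel <- function(x) dim(x$values)

subject_ids <- function(panel) rownames(panel$values)
metabolite_ids <- function(panel) colnames(panel$values)

# Processing-state guard: every preprocessing operation declares which prior
# steps it requires and which make it invalid, so out-of-order chains fail
# loudly instead of silently producing a differently-normalised panel.
check_state <- function(panel, op, platform = NULL, require = character(),
                        forbid = character()) {
  if (!inherits(panel, "metabolite_panel"))
    stop(sprintf("%s: input is not a metabolite_panel", op))
  if (!is.null(platform) && panel$platform != platform)
    stop(sprintf("%s: requires a %s panel, got %s", op, platform, panel$platform))
  missing_req <- setdiff(require, panel$steps)
  if (length(missing_req))
    stop(sprintf("%s: must be preceded by step(s): %s", op,
                 paste(missing_req, collapse = ", ")))
  bad <- intersect(forbid, panel$steps)
  if (length(bad))
    stop(sprintf("%s: cannot be applied after step(s): %s", op,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

record_step <- function(panel, step) {
  panel$steps <- c(panel$steps, step)
  panel
}
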