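#' Construct a PanelExperiment
#'
#' @param values numeric matrix, samples x analytes (rows are samples, as in
#'   a wide CSV export of a bead-panel run). Stored internally in the
#'   Bioconductor orientation (analytes x samples).
#' @param sampleData data.frame with one row per sample: `sample_id`,
#'   `group`, and optionally `duration` and `batch`.
#' @param analyteData data.frame with one row per analyte: `name`, `panel`,
#'   `in_linear_range`. Defaults to a single panel with all analytes usable.
#' @param zscored logical flag: set by [zscorePanel()], `FALSE` for raw data.
#'
#' @return A [PanelExperiment-class] object.
#' @examples
#' set.seed(1)
#' vals <- matrix(exp(rnorm(24)), 6, 4,
#'                dimnames = list(paste0("S", 1:6), paste0("A", 1:4)))
#' pe <- PanelExperiment(vals,
#'   sampleData = data.frame(sample_id = rownames(vals),
#'                           group = rep(c("40Hz", "random"), each = 3)))
#' pe
#' @export
PanelExperiment <- function(values, sampleData, analyteData = NULL,
                            zscored = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sampleData$sample_id
  if (is.null(analyteData)) {
    analyteData <- data.frame(name = colnames(values), panel = "panel",
                              in_linear_range = TRUE)
  }
  if (!identical(colnames(values), analyteData$name))
    values <- values[, analyteData$name, drop = FALSE]
  if (!"duration" %in% colnames(sampleData)) sampleData$duration <- "all"
  if (!"batch" %in% colnames(sampleData)) sampleData$batch <- "b1"
  cd <- S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id)
  rd <- S4Vectors::DataFrame(analyteData, row.names = analyteData$name)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(values)), colData = cd, rowData = rd,
    metadata = list(zscored = zscored))
  methods::new("PanelExperiment", se)
}

#' Sample-by-analyte measurement matrix
#'
#' @param x A [PanelExperiment-class].
#' @return Numeric matrix, samples in rows, analytes in columns.
#' @export
panelMatrix <- function(x) t(SummarizedExperiment::assay(x, "exprs"))

#' Per-sample metadata accessors
#'
#' @param x A [PanelExperiment-class].
#' @return `sampleGroups`, `sampleDurations`, `sampleBatches` return factors
#'   over the samples; `analytePanels` a character vector over analytes;
#'   `inLinearRange` a logical vector over analytes; `isZscored` a single
#'   logical.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
sampleGroups <- function(x) factor(SummarizedExperiment::colData(x)$group)

#' @rdname panel-accessors
#' @export
sampleDurations <- function(x) factor(SummarizedExperiment::colData(x)$duration)

#' @rdname panel-accessors
#' @export
sampleBatches <- function(x) factor(SummarizedExperiment::colData(x)$batch)

#' @rdname panel-accessors
#' @export
analytePanels <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$panel),
                  rownames(x))
}

#' @rdname panel-accessors
#' @export
inLinearRange <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$in_linear_range,
                  rownames(x))
}

#' @rdname panel-accessors
#' @export
isZscored <- function(x) isTRUE(S4Vectors::metadata(x)$zscored)

## rebuild a PanelExperiment from a (possibly subset/transformed)
## sample x analyte matrix, inheriting metadata from a template
rebuildPanel <- function(template, values, zscored = isZscored(template)) {
  sd <- as.data.frame(SummarizedExperiment::colData(template))
  sd <- sd[rownames(values), , drop = FALSE]
  rd <- as.data.frame(SummarizedExperiment::rowData(template))
  rd <- rd[colnames(values), , drop = FALSE]
  PanelExperiment(values, sampleData = sd, analyteData = rd,
                  zscored = zscored)
}

setMethod("show", "PanelExperiment", function(object) {
  cat(sprintf("PanelExperiment: %d analytes x %d samples%s\n",
              nrow(object), ncol(object),
              if (isZscored(object)) " (z-scored)" else ""))
  cat("  groups:   ",
      paste(sprintf("%s (%d)", levels(sampleGroups(object)),
                    table(sampleGroups(object))), collapse = ", "), "\n")
  d <- levels(sampleDurations(object))
  if (!identical(d, "all"))
    cat("  durations:", paste(d, collapse = ", "), "\n")
  b <- levels(sampleBatches(object))
  if (length(b) > 1L) cat("  batches:  ", paste(b, collapse = ", "), "\n")
  cat("  panels:   ",
      paste(sprintf("%s (%d)", names(table(analytePanels(object))),
                    table(analytePanels(object))), collapse = ", "), "\n")
  nOut <- sum(!inLinearRange(object))
  if (nOut) cat("  analytes outside linear range:", nOut, "\n")
})

#' Subset a PanelExperiment by condition
#'
#' Convenience subsetting by group and/or duration label, as used to select
#' the samples entering one analysis (e.g., one exposure duration).
#'
#' @param x A [PanelExperiment-class].
#' @param group,duration optional label(s) to retain.
#' @param usableOnly drop analytes flagged outside the linear range.
#' @return A [PanelExperiment-class] with the selected samples/analytes.
#' @export
subsetPanel <- function(x, group = NULL, duration = NULL, usableOnly = FALSE) {
  keep <- rep(TRUE, ncol(x))
  if (!is.null(group)) keep <- keep & sampleGroups(x) %in% group
  if (!is.null(duration)) keep <- keep & sampleDurations(x) %in% duration
  rows <- if (usableOnly) inLinearRange(x) else rep(TRUE, nrow(x))
  rebuildPanel(x, panelMatrix(x)[keep, rows, drop = FALSE])
}

#' Read / write wide-format panel CSVs
#'
#' The on-disk format is one row per sample with leading metadata columns
#' `sample_id`, `group`, `duration`, `batch` followed by one column per
#' analyte. Analyte metadata (panel membership, linear-range flag) travels
#' in a separate long CSV with columns `name`, `panel`, `in_linear_range`.
#'
#' @param x A [PanelExperiment-class].
#' @param path CSV path for the measurements.
#' @param analytePath optional CSV path for the analyte metadata.
#' @return `writePanelCsv` returns `path` invisibly; `readPanelCsv` a
#'   [PanelExperiment-class].
#' @export
writePanelCsv <- function(x, path, analytePath = NULL) {
  df <- cbind(
    as.data.frame(SummarizedExperiment::colData(x))[
      , c("sample_id", "group", "duration", "batch"), drop = FALSE],
    as.data.frame(panelMatrix(x), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(analytePath)) {
    utils::write.csv(as.data.frame(SummarizedExperiment::rowData(x)),
                     analytePath, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writePanelCsv
#' @param zscored passed to [PanelExperiment()].
#' @export
readPanelCsv <- function(path, analytePath = NULL, zscored = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- intersect(c("sample_id", "group", "duration", "batch"),
                    colnames(df))
  vals <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  rownames(vals) <- df$sample_id
  ad <- if (!is.null(analytePath)) utils::read.csv(analytePath) else NULL
  PanelExperiment(vals, sampleData = df[, meta, drop = FALSE],
                  analyteData = ad, zscored = zscored)
}
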