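#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with enforced monotonicity; the family size is the
#' input length. Thin wrapper over `stats::p.adjust(method = "BH")` with
#' input validation, exported so the network family adjustment has a single
#' named entry point.
#'
#' @param p numeric raw p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-sample analyte correlation network
#'
#' Computes the Pearson correlation of every analyte pair across the
#' samples of one condition subset, its two-sided p-value from the t
#' transform with n - 2 degrees of freedom, and BH q-values over the full
#' pair family; edges are retained at `q < qThreshold` and annotated
#' within- versus between-pathway using the panel labels. This captures
#' analytes whose levels increase or decrease together across animals.
#'
#' Constant analytes in the subset have undefined correlations; they are
#' dropped from the family with a warning.
#'
#' @param x A [PanelExperiment-class] (raw or z-scored; correlations are
#'   scale-invariant). Analytes flagged outside the linear range are
#'   excluded.
#' @param group,duration optional condition labels defining the subset.
#' @param qThreshold FDR threshold (default 0.1).
#' @return A [CorrelationNetwork-class].
#' @export
correlationNetwork <- function(x, group = NULL, duration = NULL,
                               qThreshold = 0.1) {
  sub <- subsetPanel(x, group = group, duration = duration,
                     usableOnly = TRUE)
  m <- panelMatrix(sub)
  n <- nrow(m)
  if (n < 4L) stopf("correlation network needs >= 4 samples (got %d)", n)
  if (ncol(m) < 2L) stopf("need >= 2 analytes")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds < .Machine$double.eps]
  if (length(dropped)) {
    warning(sprintf("constant analyte(s) excluded from family: %s",
                    paste(dropped, collapse = ", ")))
    m <- m[, sds >= .Machine$double.eps, drop = FALSE]
  }
  pathway <- analytePanels(sub)[colnames(m)]
  cm <- stats::cor(m)
  cmb <- utils::combn(colnames(m), 2)
  r <- cm[cbind(cmb[1, ], cmb[2, ])]
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * Inf
  p <- 2 * stats::pt(-abs(tt), n - 2)
  q <- bhAdjust(p)
  within <- pathway[cmb[1, ]] == pathway[cmb[2, ]]
  cls <- ifelse(within, paste0("within-", pathway[cmb[1, ]]), "between")
  allPairs <- data.frame(analyte1 = cmb[1, ], analyte2 = cmb[2, ], r = r,
                         p = p, q = q, sign = sign(r),
                         withinPathway = within, class = cls)
  methods::new("CorrelationNetwork",
    edges = allPairs[allPairs$q < qThreshold, , drop = FALSE],
    allPairs = allPairs,
    nodes = data.frame(analyte = colnames(m), pathway = unname(pathway)),
    nSamples = n, nComparisons = ncol(cmb), qThreshold = qThreshold,
    droppedAnalytes = dropped)
}

#' Significant-edge counts by pathway class
#'
#' Tallies the significant edges within each pathway and between pathways,
#' reproducing count-style reporting ("k significant correlations in the
#' NF-kB pathway, ...").
#'
#' @param net A [CorrelationNetwork-class].
#' @return named integer vector: one `within-<pathway>` count per pathway
#'   present among the nodes, a `between` count, and `total`.
#' @export
networkSummary <- function(net) {
  classes <- c(paste0("within-", sort(unique(net@nodes$pathway))), "between")
  counts <- vapply(classes, function(cl) sum(net@edges$class == cl),
                   integer(1))
  c(counts, total = nrow(net@edges))
}

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork: %d nodes, %d/%d pairs at q < %g (n = %d)\n",
              nrow(object@nodes), nrow(object@edges), object@nComparisons,
              object@qThreshold, object@nSamples))
  if (length(object@droppedAnalytes))
    cat("  dropped constant analytes:",
        paste(object@droppedAnalytes, collapse = ", "), "\n")
})

#' Write a network edge list as TSV
#'
#' Writes the significant edges (or, with `all = TRUE`, the full tested
#' family) as `node1, node2, r, p, q, class` TSV.
#'
#' @param net A [CorrelationNetwork-class].
#' @param path output path.
#' @param all write the full family instead of significant edges only.
#' @return `path`, invisibly.
#' @export
writeNetworkTsv <- function(net, path, all = FALSE) {
  df <- if (all) net@allPairs else net@edges
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
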