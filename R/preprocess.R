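#' Drop analytes outside the assay's linear range
#'
#' Bead fluorescence is only proportional to concentration inside the
#' assay's linear range; analytes flagged `in_linear_range = FALSE` are
#' removed from the panel before any analysis.
#'
#' @param x A [PanelExperiment-class].
#' @return `list(panel=, report=)` where `report` is a
#'   [CleaningReport-class] naming the excluded analytes.
#' @export
excludeOutOfRange <- function(x) {
  flag <- inLinearRange(x)
  if (!any(flag)) stopf("all %d analytes fall outside the linear range",
                        length(flag))
  report <- methods::new("CleaningReport",
    excludedAnalytes = data.frame(analyte = names(flag)[!flag],
                                  reason = rep("outside linear range",
                                               sum(!flag))),
    removedSamples = emptyRemoved(), batchCoefficients = NULL)
  panel <- if (all(flag)) x else
    rebuildPanel(x, panelMatrix(x)[, flag, drop = FALSE])
  list(panel = panel, report = report)
}

emptyRemoved <- function() {
  data.frame(sample_id = character(), iteration = integer(),
             distance = numeric(), cutoff = numeric())
}

zscoreMatrix <- function(m) {
  if (nrow(m) < 2L) stopf("z-scoring needs >= 2 samples")
  sds <- apply(m, 2, stats::sd)
  const <- sds < .Machine$double.eps^0.5 * pmax(1, abs(colMeans(m)))
  if (any(const))
    stopf("constant analyte column(s): %s",
          paste(colnames(m)[const], collapse = ", "))
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Z-score a panel analyte-wise
#'
#' Centers and scales each analyte across samples to mean 0 and unit sample
#' SD (n - 1 denominator). Idempotent to numerical tolerance. A constant
#' analyte signals a degenerate assay and raises an error naming it.
#'
#' @param x A [PanelExperiment-class].
#' @return A z-scored [PanelExperiment-class] (`isZscored()` is `TRUE`).
#' @export
zscorePanel <- function(x) {
  m <- zscoreMatrix(panelMatrix(x))
  attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
  rebuildPanel(x, m, zscored = TRUE)
}

#' Remove additive batch effects while preserving group differences
#'
#' Fits, per analyte, a least-squares model with the stimulation group and
#' the batch as additive factors (sum-to-zero batch contrasts) and subtracts
#' only the fitted batch component. Because the group term stays in the
#' model, group-mean differences are preserved even for unbalanced
#' batch/group layouts, unlike naive per-batch centering.
#'
#' @param x A z-scored [PanelExperiment-class] with >= 2 batches.
#' @return `list(panel=, report=)`; the report's `batchCoefficients` slot
#'   holds the removed per-analyte batch coefficients (batches x analytes).
#' @export
removeBatchEffects <- function(x) {
  batch <- droplevels(sampleBatches(x))
  group <- droplevels(sampleGroups(x))
  if (nlevels(batch) < 2L) stopf("batch correction needs >= 2 batches")
  mmG <- stats::model.matrix(~group)
  mmB <- stats::model.matrix(~batch,
    contrasts.arg = list(batch = "contr.sum"))[, -1, drop = FALSE]
  mm <- cbind(mmG, mmB)
  if (qr(mm)$rank < ncol(mm))
    stopf("batch is confounded with group; batch effect unidentifiable")
  m <- panelMatrix(x)
  beta <- qr.coef(qr(mm), m)
  bIdx <- seq.int(ncol(mmG) + 1L, ncol(mm))
  corrected <- m - mmB %*% beta[bIdx, , drop = FALSE]
  ## expand sum-contrast coefficients to one row per batch level
  coefB <- rbind(beta[bIdx, , drop = FALSE],
                 -colSums(beta[bIdx, , drop = FALSE]))
  rownames(coefB) <- levels(batch)
  report <- methods::new("CleaningReport",
    excludedAnalytes = data.frame(analyte = character(),
                                  reason = character()),
    removedSamples = emptyRemoved(), batchCoefficients = coefB)
  list(panel = rebuildPanel(x, corrected), report = report)
}

#' Iterative PCA/Mahalanobis outlier removal
#'
#' Repeats until convergence: z-score the remaining samples, run PCA, and
#' compute each sample's squared Mahalanobis distance in the space of the
#' leading `nComponents` principal-component scores; samples whose squared
#' distance exceeds the confidence-ellipse cutoff are removed. The default
#' cutoff is the chi-square quantile with `nComponents` degrees of freedom
#' (the asymptotic ellipse); `method = "beta"` uses the exact small-sample
#' beta quantile for internally studentized distances.
#'
#' The loop terminates because each iteration either removes at least one
#' sample or exits; it aborts when fewer than `nComponents + 2` samples
#' would remain (a sign of over-aggressive removal).
#'
#' @param x A [PanelExperiment-class] (z-scored internally each iteration).
#' @param confidence ellipse confidence level in (0.9, 1); default 0.995.
#' @param nComponents leading PCs defining the ellipse space (default 2).
#' @param method `"chisq"` (default) or `"beta"` cutoff.
#' @return `list(panel=, report=)`; the report records each removed sample
#'   with its iteration, squared distance, and the cutoff it exceeded.
#' @export
removeOutliers <- function(x, confidence = 0.995, nComponents = 2L,
                           method = c("chisq", "beta")) {
  method <- match.arg(method)
  if (confidence <= 0.9 || confidence >= 1)
    stopf("confidence must lie in (0.9, 1)")
  m <- panelMatrix(x)
  if (nrow(m) <= nComponents)
    stopf("need more samples than components")
  removed <- emptyRemoved()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    n <- nrow(m)
    if (n < nComponents + 2L)
      stopf("outlier removal left %d samples (< nComponents + 2); aborting",
            n)
    z <- zscoreMatrix(m)
    pr <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    k <- min(nComponents, sum(pr$sdev > 1e-10))
    sc <- pr$x[, seq_len(k), drop = FALSE]
    d2 <- stats::mahalanobis(sc, colMeans(sc), stats::cov(sc))
    cutoff <- switch(method,
      chisq = stats::qchisq(confidence, df = k),
      beta = (n - 1)^2 / n *
        stats::qbeta(confidence, k / 2, (n - k - 1) / 2))
    out <- d2 > cutoff
    if (!any(out)) break
    removed <- rbind(removed, data.frame(
      sample_id = rownames(m)[out], iteration = iter,
      distance = d2[out], cutoff = cutoff))
    m <- m[!out, , drop = FALSE]
  }
  rownames(removed) <- NULL
  report <- methods::new("CleaningReport",
    excludedAnalytes = data.frame(analyte = character(),
                                  reason = character()),
    removedSamples = removed, batchCoefficients = NULL)
  list(panel = rebuildPanel(x, m), report = report)
}

#' Full preprocessing chain
#'
#' Applies, in a fixed order: linear-range exclusion, z-scoring,
#' design-aware batch correction (skipped with a message on single-batch
#' data), re-z-scoring of the batch-corrected values, iterative
#' Mahalanobis-ellipse outlier removal, and a final re-z-score so the
#' returned panel satisfies the z-scored precondition of [fitPlsda()].
#'
#' @param x A raw [PanelExperiment-class].
#' @param batchCorrect,outlierRemove stage toggles.
#' @param confidence,nComponents,method passed to [removeOutliers()].
#' @return `list(panel=, report=)` with a merged [CleaningReport-class].
#' @export
preprocessPanel <- function(x, batchCorrect = TRUE, outlierRemove = TRUE,
                            confidence = 0.995, nComponents = 2L,
                            method = "chisq") {
  st <- excludeOutOfRange(x)
  panel <- zscorePanel(st$panel)
  excluded <- st$report@excludedAnalytes
  coefB <- NULL
  if (batchCorrect) {
    if (nlevels(droplevels(sampleBatches(panel))) < 2L) {
      message("single batch: batch correction skipped")
    } else {
      bc <- removeBatchEffects(panel)
      panel <- zscorePanel(bc$panel)
      coefB <- bc$report@batchCoefficients
    }
  }
  removed <- emptyRemoved()
  if (outlierRemove) {
    ol <- removeOutliers(panel, confidence = confidence,
                         nComponents = nComponents, method = method)
    panel <- zscorePanel(ol$panel)
    removed <- ol$report@removedSamples
  }
  report <- methods::new("CleaningReport",
    excludedAnalytes = excluded, removedSamples = removed,
    batchCoefficients = coefB)
  list(panel = panel, report = report)
}

#' Serialize a cleaning report as JSON
#'
#' @param report A [CleaningReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCleaningReportJson <- function(report, path) {
  jsonlite::write_json(list(
    excluded_analytes = report@excludedAnalytes,
    removed_samples = report@removedSamples,
    batch_coefficients = if (is.null(report@batchCoefficients)) NULL
      else as.data.frame(report@batchCoefficients)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
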