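#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' PanelExperiment: a multiplexed bead-panel measurement container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the conventions
#' used throughout this package: rows are analytes (cytokines or
#' phosphoproteins), columns are samples (animals, possibly crossed with an
#' exposure duration). `rowData` carries per-analyte metadata (`panel`
#' membership and the `in_linear_range` assay-validity flag); `colData`
#' carries per-sample metadata (`group`, `duration`, `batch`).
#'
#' Raw panels hold strictly positive concentration-scale values; after
#' [zscorePanel()] the object is flagged (`isZscored()`) and columns of the
#' sample-by-analyte matrix have mean 0 and unit sample SD.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [PanelExperiment()], [panelMatrix()], [zscorePanel()]
#' @export
setClass("PanelExperiment", contains = "SummarizedExperiment")

setValidity("PanelExperiment", function(object) {
  msg <- character()
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!all(is.finite(m)))
      msg <- c(msg, "measurements must be finite")
    else if (!isTRUE(S4Vectors::metadata(object)$zscored) && any(m <= 0))
      msg <- c(msg, "raw (non z-scored) measurements must be strictly positive")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample_ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate analyte names")
  if (!("group" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Synthetic-panel experimental design
#'
#' Describes the shape of a synthetic bead-panel experiment: the stimulation
#' groups, per-group (and optionally per-duration) animal counts, the analyte
#' roster with panel membership and linear-range validity, the number of
#' assay batches (cohorts), and the RNG seed that makes generation
#' reproducible.
#'
#' @slot groups character, group labels (>= 2).
#' @slot nPerGroup numeric matrix, groups x durations sample counts (a single
#'   column named `"all"` when there is no duration factor); all entries >= 2
#'   or 0 (0 marks a cell not run).
#' @slot analytes data.frame with columns `name`, `panel`, `in_linear_range`.
#' @slot durations character, duration labels (may be empty).
#' @slot nBatches integer >= 1.
#' @slot seed integer RNG seed.
#' @seealso [PanelDesign()], [generatePanel()]
#' @export
setClass("PanelDesign", representation(
  groups = "character", nPerGroup = "matrix", analytes = "data.frame",
  durations = "character", nBatches = "integer", seed = "integer"))

setValidity("PanelDesign", function(object) {
  msg <- character()
  if (length(object@groups) < 2L)
    msg <- c(msg, "groups: at least 2 stimulation groups required")
  n <- object@nPerGroup
  if (!is.numeric(n) || nrow(n) != length(object@groups))
    msg <- c(msg, "nPerGroup: must have one row per group")
  else if (any(n != 0 & n < 2))
    msg <- c(msg, "nPerGroup: every non-empty cell needs >= 2 animals")
  a <- object@analytes
  need <- c("name", "panel", "in_linear_range")
  if (!all(need %in% colnames(a)))
    msg <- c(msg, "analytes: need columns name, panel, in_linear_range")
  else if (anyDuplicated(a$name))
    msg <- c(msg, "analytes: names must be unique")
  if (object@nBatches < 1L)
    msg <- c(msg, "nBatches: must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Planted effects for synthetic panels
#'
#' The generative effects injected on the log scale: per-(group, analyte)
#' mean shifts, per-(batch, analyte) offsets, correlated analyte blocks
#' driven by per-sample latent factors, i.i.d. Gaussian noise, and
#' whole-sample outliers.
#'
#' The measurement model for sample \eqn{i} (group \eqn{g}, batch \eqn{b})
#' and analyte \eqn{j} is
#' \deqn{\log x_{ij} = \mu_j + s_{gj} + o_{bj} + \sum_k \lambda_{kj} f_{ki}
#'   + \epsilon_{ij},\quad \epsilon_{ij} \sim N(0, \sigma^2),}
#' with \eqn{f_{ki} \sim N(0,1)} one latent factor per correlated block, and
#' outlier samples additionally shifted by `outlierMagnitude * noiseSd` on
#' every analyte.
#'
#' @slot groupShifts numeric matrix groups x analytes (log-scale shifts).
#' @slot batchOffsets numeric matrix batches x analytes (log-scale offsets).
#' @slot blocks list of `list(analytes=, loading=)` correlated blocks;
#'   |loading| <= 1.
#' @slot noiseSd positive numeric, log-scale noise SD.
#' @slot outlierFraction numeric in [0, 0.5).
#' @slot outlierMagnitude positive numeric (multiple of noiseSd).
#' @seealso [PanelEffects()], [generatePanel()]
#' @export
setClass("PanelEffects", representation(
  groupShifts = "matrix", batchOffsets = "matrix", blocks = "list",
  noiseSd = "numeric", outlierFraction = "numeric",
  outlierMagnitude = "numeric"))

setValidity("PanelEffects", function(object) {
  msg <- character()
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd: must be > 0")
  if (object@outlierFraction < 0 || object@outlierFraction >= 0.5)
    msg <- c(msg, "outlierFraction: must lie in [0, 0.5)")
  if (object@outlierMagnitude <= 0)
    msg <- c(msg, "outlierMagnitude: must be > 0")
  for (bl in object@blocks) {
    if (!all(c("analytes", "loading") %in% names(bl)))
      msg <- c(msg, "blocks: each block needs $analytes and $loading")
    else if (any(abs(bl$loading) > 1))
      msg <- c(msg, "blocks: |loading| must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a generated panel
#'
#' Records every effect injected by [generatePanel()] so downstream stages
#' (loading recovery, outlier rejection, batch correction, correlation
#' networks) can be validated against known truth.
#'
#' @slot discriminatingAnalytes named list: per group, the analytes with a
#'   nonzero planted mean shift.
#' @slot correlatedPairs data.frame (`analyte1`, `analyte2`) of pairs with a
#'   nonzero latent-factor loading product.
#' @slot outlierSamples character, sample_ids of planted outliers.
#' @slot groupShifts,batchOffsets the injected log-scale effect matrices.
#' @export
setClass("PanelGroundTruth", representation(
  discriminatingAnalytes = "list", correlatedPairs = "data.frame",
  outlierSamples = "character", groupShifts = "matrix",
  batchOffsets = "matrix"))

#' Cleaning report of the preprocessing chain
#'
#' @slot excludedAnalytes data.frame (`analyte`, `reason`).
#' @slot removedSamples data.frame (`sample_id`, `iteration`, `distance`,
#'   `cutoff`): every sample removed by the iterative Mahalanobis ellipse,
#'   with the squared distance that exceeded the cutoff at that iteration.
#' @slot batchCoefficients per-analyte batch coefficients removed (batches x
#'   analytes matrix), or NULL when no batch correction was applied.
#' @export
setClass("CleaningReport", representation(
  excludedAnalytes = "data.frame", removedSamples = "data.frame",
  batchCoefficients = "ANY"))

setValidity("CleaningReport", function(object) {
  rs <- object@removedSamples
  if (nrow(rs) && any(rs$distance <= rs$cutoff))
    "removedSamples: every removal must exceed its cutoff" else TRUE
})

#' Fitted (and optionally rotated) PLS-DA model
#'
#' Supervised latent-variable model fitted by NIPALS PLS2 against a one-hot
#' group encoding. `loadings` are the unit-norm weight vectors (analytes x
#' LVs, mutually orthogonal); `scores` are the NIPALS sample scores
#' (samples x LVs, mutually orthogonal columns). After [rotateLvPlane()],
#' `rotationAngle` holds the planar rotation applied jointly to the
#' (LV1, LV2) loadings and scores, and `separation` the per-LV
#' between/within variance ratio of scores under `contrast`.
#'
#' @slot loadings analytes x LVs matrix, unit-norm orthogonal columns.
#' @slot scores samples x LVs NIPALS score matrix.
#' @slot groups factor of sample group labels.
#' @slot nLv integer, number of latent variables.
#' @slot rotationAngle numeric radians (0 before rotation).
#' @slot contrast character: `"all"` or a designated group (one-vs-rest).
#' @slot separation numeric per-LV separation statistic (may be `Inf`;
#'   see `separationCapped`).
#' @slot separationCapped logical per-LV flag: `TRUE` when within-group
#'   variance was 0 and the statistic is reported as `Inf`.
#' @export
setClass("PlsdaModel", representation(
  loadings = "matrix", scores = "matrix", groups = "factor",
  nLv = "integer", rotationAngle = "numeric", contrast = "character",
  separation = "numeric", separationCapped = "logical"))

setValidity("PlsdaModel", function(object) {
  msg <- character()
  W <- object@loadings
  nrm <- sqrt(colSums(W^2))
  if (any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "loading columns must be unit norm")
  if (ncol(W) >= 2L) {
    cp <- crossprod(W)
    if (max(abs(cp[upper.tri(cp)])) > 1e-6)
      msg <- c(msg, "loading columns must be mutually orthogonal")
  }
  if (nrow(object@scores) != length(object@groups))
    msg <- c(msg, "scores rows must match group labels")
  if (length(msg)) msg else TRUE
})

#' Group-separation statistic of a score axis
#'
#' Between/within variance ratio (mean-square form) of 1-D scores under a
#' contrast: all groups, or one designated group versus the pooled rest.
#'
#' @slot statistic numeric >= 0 (`Inf` when within-variance is 0; see
#'   `capped`).
#' @slot perGroupMeans named numeric, mean score per group.
#' @slot capped logical, degenerate perfect-separation flag.
#' @slot contrast character.
#' @export
setClass("GroupSeparation", representation(
  statistic = "numeric", perGroupMeans = "numeric", capped = "logical",
  contrast = "character"))

setValidity("GroupSeparation", function(object) {
  if (!object@capped && object@statistic < 0)
    "statistic must be >= 0" else TRUE
})

#' Leave-one-out loading-stability envelope
#'
#' Mean and SD of the rotated-LV1 loadings across leave-one-out refits of
#' the full fit-and-rotate procedure, each refit sign-aligned to the
#' full-data LV1 (the error bars on weighted-profile plots).
#'
#' @slot envelope data.frame (`analyte`, `mean`, `sd`).
#' @slot nRefits integer, total refits accumulated (cycling LOO).
#' @slot alignmentFlips integer, refits whose sign was flipped during
#'   alignment.
#' @slot skippedSamples character, samples whose exclusion would leave a
#'   group with < 2 members (their refits are skipped with a warning).
#' @slot reference numeric, the full-data rotated-LV1 loading vector used
#'   for alignment.
#' @export
setClass("LoadingEnvelope", representation(
  envelope = "data.frame", nRefits = "integer", alignmentFlips = "integer",
  skippedSamples = "character", reference = "numeric"))

setValidity("LoadingEnvelope", function(object) {
  if (nrow(object@envelope) && any(object@envelope$sd < 0))
    "envelope SDs must be >= 0" else TRUE
})

#' Label-permutation test result
#'
#' @slot observed numeric, rotated-LV1 separation statistic on true labels.
#' @slot nullStats numeric length-B null distribution from label shuffles
#'   (full fit + rotation re-run per shuffle).
#' @slot pValue numeric, add-one empirical p: `(1 + #(null >= obs))/(B + 1)`.
#' @slot B integer, number of shuffles.
#' @slot seed integer.
#' @export
setClass("PermutationResult", representation(
  observed = "numeric", nullStats = "numeric", pValue = "numeric",
  B = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@nullStats) != object@B)
    msg <- c(msg, "nullStats must have length B")
  if (object@pValue < 1 / (object@B + 1) - 1e-12 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [1/(B+1), 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-sample analyte correlation network
#'
#' All-pairs Pearson correlations across samples of one condition subset,
#' with BH-FDR q-values over the full pair family and edges retained at
#' q < threshold, each annotated within- versus between-pathway.
#'
#' @slot edges data.frame (`analyte1`, `analyte2`, `r`, `p`, `q`, `sign`,
#'   `withinPathway`, `class`) of significant pairs.
#' @slot allPairs data.frame, the full tested family (same columns).
#' @slot nodes data.frame (`analyte`, `pathway`).
#' @slot nSamples integer used for the correlations.
#' @slot nComparisons integer, family size (C(nodes, 2) minus dropped).
#' @slot qThreshold numeric.
#' @slot droppedAnalytes character, constant analytes excluded from the
#'   family.
#' @export
setClass("CorrelationNetwork", representation(
  edges = "data.frame", allPairs = "data.frame", nodes = "data.frame",
  nSamples = "integer", nComparisons = "integer", qThreshold = "numeric",
  droppedAnalytes = "character"))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  ap <- object@allPairs
  if (nrow(ap)) {
    if (any(abs(ap$r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
    if (any(ap$q < ap$p - 1e-12)) msg <- c(msg, "q must be >= p")
  }
  if (nrow(object@edges) && any(object@edges$q >= object@qThreshold))
    msg <- c(msg, "edges must satisfy q < threshold")
  if (length(msg)) msg else TRUE
})
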