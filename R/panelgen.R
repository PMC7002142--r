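#' Analyte rosters for the emulated study panels
#'
#' `cytokineAnalytes()` returns the 32-plex mouse cytokine/chemokine roster;
#' `phosphoAnalytes()` the combined NF-kB 6-plex and MAPK panel roster with
#' the linear-range validity flags (c-Myc, p-IkBa, p-HSP27, p-p38 and p-p53
#' fell outside the assay's linear range and are flagged unusable).
#' p-STAT1 is included as a tenth MAPK-panel analyte; it is reported with
#' the MAPK pathway although it is not part of the printed kit roster.
#'
#' @return data.frame with columns `name`, `panel`, `in_linear_range`.
#' @export
cytokineAnalytes <- function() {
  nm <- c("Eotaxin", "G-CSF", "GM-CSF", "IFN-g", "IL-1a", "IL-1b", "IL-2",
          "IL-3", "IL-4", "IL-5", "IL-6", "IL-7", "IL-9", "IL-10",
          "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17", "IP-10", "KC",
          "LIF", "LIX", "MCP-1", "M-CSF", "MIG", "MIP-1a", "MIP-1b",
          "MIP-2", "RANTES", "TNF-a", "VEGF")
  data.frame(name = nm, panel = "cytokine", in_linear_range = TRUE)
}

#' @rdname cytokineAnalytes
#' @export
phosphoAnalytes <- function() {
  rbind(
    data.frame(name = c("c-Myc", "p-FADD", "p-IkBa", "p-IKKa/b", "p-NFkB",
                        "TNFR1"),
               panel = "nfkb",
               in_linear_range = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)),
    data.frame(name = c("p-ATF2", "p-Erk", "p-HSP27", "p-JNK", "p-c-Jun",
                        "p-MEK1", "p-MSK1", "p-p38", "p-p53", "p-STAT1"),
               panel = "mapk",
               in_linear_range = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                   TRUE, FALSE, FALSE, TRUE)))
}

#' Construct a synthetic-panel design
#'
#' @param groups character group labels (>= 2).
#' @param nPerGroup animals per group: a scalar, a per-group vector, or a
#'   groups x durations matrix for designs crossed with exposure duration.
#' @param analytes analyte roster data.frame (`name`, `panel`,
#'   `in_linear_range`); plain character names are accepted and wrapped.
#' @param durations optional duration labels.
#' @param nBatches number of assay batches (cohorts).
#' @param seed RNG seed governing generation.
#' @return A [PanelDesign-class].
#' @examples
#' PanelDesign(c("40Hz", "20Hz", "random", "light"), 6, cytokineAnalytes())
#' @export
PanelDesign <- function(groups, nPerGroup, analytes, durations = character(),
                        nBatches = 1L, seed = 1L) {
  if (is.character(analytes))
    analytes <- data.frame(name = analytes, panel = "panel",
                           in_linear_range = TRUE)
  nd <- max(1L, length(durations))
  if (!is.matrix(nPerGroup)) {
    nPerGroup <- matrix(nPerGroup, nrow = length(groups), ncol = nd)
  }
  dimnames(nPerGroup) <- list(groups, if (length(durations)) durations
                              else "all")
  methods::new("PanelDesign", groups = groups, nPerGroup = nPerGroup,
               analytes = analytes, durations = as.character(durations),
               nBatches = as.integer(nBatches), seed = as.integer(seed))
}

#' Construct planted effects for a design
#'
#' @param design A [PanelDesign-class] (supplies group/analyte/batch names).
#' @param groupShifts named list: per group, a named numeric vector of
#'   log-scale mean shifts on a subset of analytes.
#' @param batchOffsets named list: per batch (`"b1"`, `"b2"`, ...), a named
#'   numeric vector of log-scale offsets; or the string `"random"` to draw
#'   one offset per (batch, analyte) from N(0, `batchSd`).
#' @param batchSd SD used when `batchOffsets = "random"`.
#' @param blocks list of correlated blocks, each
#'   `list(analytes = <names>, loading = <coefficient(s)>)`.
#' @param noiseSd log-scale measurement noise SD. The default 0.3
#'   corresponds to ~30 percent CV, typical of between-animal variability in
#'   tissue bead-panel measurements.
#' @param outlierFraction proportion of samples turned into whole-sample
#'   outliers (in [0, 0.5)).
#' @param outlierMagnitude outlier shift in multiples of `noiseSd`.
#' @return A [PanelEffects-class].
#' @export
PanelEffects <- function(design, groupShifts = list(),
                         batchOffsets = list(), batchSd = 0.3,
                         blocks = list(), noiseSd = 0.3,
                         outlierFraction = 0, outlierMagnitude = 6) {
  an <- design@analytes$name
  gs <- matrix(0, length(design@groups), length(an),
               dimnames = list(design@groups, an))
  for (g in names(groupShifts)) {
    if (!g %in% design@groups) stopf("groupShifts: unknown group '%s'", g)
    v <- groupShifts[[g]]
    bad <- setdiff(names(v), an)
    if (length(bad)) stopf("groupShifts: unknown analyte(s) %s",
                           paste(bad, collapse = ", "))
    gs[g, names(v)] <- v
  }
  bn <- paste0("b", seq_len(design@nBatches))
  bo <- matrix(0, design@nBatches, length(an), dimnames = list(bn, an))
  if (identical(batchOffsets, "random")) {
    ## drawn at generation time (seeded there); mark with NA sentinel
    bo[] <- NA_real_
    attr(bo, "randomSd") <- batchSd
  } else {
    for (b in names(batchOffsets)) {
      if (!b %in% bn) stopf("batchOffsets: unknown batch '%s'", b)
      v <- batchOffsets[[b]]
      bo[b, names(v)] <- v
    }
  }
  for (bl in blocks) {
    bad <- setdiff(bl$analytes, an)
    if (length(bad)) stopf("blocks: unknown analyte(s) %s",
                           paste(bad, collapse = ", "))
  }
  methods::new("PanelEffects", groupShifts = gs, batchOffsets = bo,
               blocks = blocks, noiseSd = noiseSd,
               outlierFraction = outlierFraction,
               outlierMagnitude = outlierMagnitude)
}

#' Generate a synthetic bead-panel table with known ground truth
#'
#' Measurements are generated as the exponential of a Gaussian log-scale
#' model (see [PanelEffects-class]): per-analyte baseline + planted group
#' shift + batch offset + latent-factor block term + noise, so values are
#' strictly positive and right-skewed as bead-assay concentrations are.
#' Batches are assigned round-robin within each group x duration cell, so
#' batch is never confounded with group. Outlier samples (a fixed count,
#' `round(outlierFraction * n)`, chosen at random) are shifted on every
#' analyte by `outlierMagnitude * noiseSd`. Identical seeds give identical
#' output.
#'
#' @param design A [PanelDesign-class].
#' @param effects A [PanelEffects-class]; defaults to no planted effects.
#' @return A list with elements `panel` (a [PanelExperiment-class]) and
#'   `truth` (a [PanelGroundTruth-class]).
#' @examples
#' d <- PanelDesign(c("40Hz", "20Hz", "random", "light"), 6,
#'                  cytokineAnalytes(), seed = 7)
#' gp <- generatePanel(d, PanelEffects(d,
#'   groupShifts = list(`40Hz` = c(`IL-6` = 0.6, MIG = 0.6))))
#' gp$panel
#' gp$truth@discriminatingAnalytes
#' @export
generatePanel <- function(design, effects = PanelEffects(design)) {
  methods::validObject(design)
  methods::validObject(effects)
  an <- design@analytes$name
  if (!identical(colnames(effects@groupShifts), an))
    stopf("effects do not match the design's analyte roster")
  durs <- if (length(design@durations)) design@durations else "all"

  ## enumerate samples
  rows <- list()
  for (d in seq_along(durs)) {
    for (g in design@groups) {
      n <- design@nPerGroup[g, d]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, duration = durs[d], idx = seq_len(n))
    }
  }
  samp <- do.call(rbind, rows)
  nS <- nrow(samp)
  samp$sample_id <- sprintf("S%03d_%s_%s", seq_len(nS), samp$group,
                            samp$duration)
  ## round-robin batch assignment within each group x duration cell
  samp$batch <- NA_character_
  for (cell in split(seq_len(nS), paste(samp$group, samp$duration))) {
    samp$batch[cell] <-
      paste0("b", ((seq_along(cell) - 1L) %% design@nBatches) + 1L)
  }

  withSeed(design@seed, {
    baseline <- stats::rnorm(length(an), mean = 2, sd = 0.5)
    bo <- effects@batchOffsets
    if (anyNA(bo)) {
      bo[] <- stats::rnorm(length(bo), 0, attr(bo, "randomSd"))
    }
    logX <- matrix(baseline, nS, length(an), byrow = TRUE)
    logX <- logX + effects@groupShifts[samp$group, , drop = FALSE]
    logX <- logX + bo[samp$batch, , drop = FALSE]
    for (bl in effects@blocks) {
      f <- stats::rnorm(nS)
      lam <- rep_len(bl$loading, length(bl$analytes))
      j <- match(bl$analytes, an)
      logX[, j] <- logX[, j] + outer(f, lam)
    }
    logX <- logX + matrix(stats::rnorm(nS * length(an), 0, effects@noiseSd),
                          nS, length(an))
    nOut <- round(effects@outlierFraction * nS)
    outIdx <- if (nOut > 0) sort(sample.int(nS, nOut)) else integer()
    if (nOut > 0)
      logX[outIdx, ] <- logX[outIdx, ] +
        effects@outlierMagnitude * effects@noiseSd
  })
  dimnames(logX) <- list(samp$sample_id, an)

  panel <- PanelExperiment(exp(logX),
    sampleData = samp[, c("sample_id", "group", "duration", "batch")],
    analyteData = design@analytes)

  disc <- lapply(stats::setNames(design@groups, design@groups), function(g)
    an[effects@groupShifts[g, ] != 0])
  pairs <- do.call(rbind, lapply(effects@blocks, function(bl) {
    lam <- rep_len(bl$loading, length(bl$analytes))
    keep <- bl$analytes[lam != 0]
    if (length(keep) < 2) return(NULL)
    cmb <- utils::combn(keep, 2)
    data.frame(analyte1 = cmb[1, ], analyte2 = cmb[2, ])
  }))
  if (is.null(pairs))
    pairs <- data.frame(analyte1 = character(), analyte2 = character())
  truth <- methods::new("PanelGroundTruth",
    discriminatingAnalytes = disc, correlatedPairs = pairs,
    outlierSamples = samp$sample_id[outIdx],
    groupShifts = effects@groupShifts, batchOffsets = bo)
  list(panel = panel, truth = truth)
}

#' Canned designs emulating the study shapes
#'
#' `cytokineDesign()`: 4 stimulation groups (40 Hz, 20 Hz, random flicker,
#' constant light) x 6 animals, the 32-plex cytokine roster, a single batch
#' (1 h exposure). `phosphoDesign()`: 2 groups (40 Hz vs random flicker) at
#' 3 exposure durations with per-duration 40 Hz group sizes defaulting to
#' the NF-kB cohort sizes (17, 12, 6; random n = 6 throughout), the combined
#' NF-kB + MAPK roster with its linear-range exclusions, across 2 batches.
#'
#' @param seed RNG seed.
#' @param n40,nRandom per-duration group sizes for the phosphoprotein
#'   design (named by duration).
#' @param nBatches batches for the phosphoprotein design.
#' @return A [PanelDesign-class].
#' @export
cytokineDesign <- function(seed = 1L) {
  PanelDesign(c("40Hz", "20Hz", "random", "light"), nPerGroup = 6,
              analytes = cytokineAnalytes(), nBatches = 1L, seed = seed)
}

#' @rdname cytokineDesign
#' @export
phosphoDesign <- function(seed = 2L,
                          n40 = c(`5min` = 17, `15min` = 12, `60min` = 6),
                          nRandom = c(`5min` = 6, `15min` = 6, `60min` = 6),
                          nBatches = 2L) {
  durs <- names(n40)
  PanelDesign(c("40Hz", "random"),
              nPerGroup = rbind(`40Hz` = n40, random = nRandom[durs]),
              analytes = phosphoAnalytes(), durations = durs,
              nBatches = nBatches, seed = seed)
}

#' Generate fixtures matching the study designs
#'
#' Produces the two synthetic datasets used throughout examples and
#' validation, with planted effects emulating the reported biology:
#' a cytokine panel whose 40 Hz group is lifted on M-CSF, IL-6, MIG and
#' IL-4 (with distinct mild signatures for the light and random groups),
#' and a phosphoprotein panel with a 40 Hz shift on p-IKKa/b, TNFR1 and
#' p-FADD, one correlated block per pathway, random batch offsets and a
#' small fraction of outlier animals.
#'
#' @param seed RNG seed (offset internally so the two panels differ).
#' @return Named list of two `list(panel=, truth=)` fixtures
#'   (`cytokine`, `phospho`).
#' @export
emulateStudyDesigns <- function(seed = 1L) {
  cd <- cytokineDesign(seed = seed)
  ce <- PanelEffects(cd,
    groupShifts = list(
      `40Hz` = c(`M-CSF` = 0.6, `IL-6` = 0.6, MIG = 0.6, `IL-4` = 0.6),
      light = c(`IL-2` = 0.45, VEGF = 0.45, `IL-9` = 0.45, `IL-1a` = 0.45,
                `IL-13` = 0.45),
      random = c(`IL-10` = 0.6)))
  pd <- phosphoDesign(seed = seed + 1000L)
  pe <- PanelEffects(pd,
    groupShifts = list(
      `40Hz` = c(`p-IKKa/b` = 0.45, TNFR1 = 0.45, `p-FADD` = 0.45)),
    batchOffsets = "random", batchSd = 0.3,
    blocks = list(
      list(analytes = c("p-FADD", "p-IKKa/b", "p-NFkB", "TNFR1"),
           loading = 0.8),
      list(analytes = c("p-MEK1", "p-MSK1", "p-Erk", "p-JNK"),
           loading = 0.8)),
    outlierFraction = 0.04, outlierMagnitude = 6)
  list(cytokine = generatePanel(cd, ce), phospho = generatePanel(pd, pe))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A [PanelGroundTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    discriminating_analytes = truth@discriminatingAnalytes,
    correlated_pairs = truth@correlatedPairs,
    outlier_samples = truth@outlierSamples,
    group_shifts = as.data.frame(truth@groupShifts),
    batch_offsets = as.data.frame(truth@batchOffsets)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
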