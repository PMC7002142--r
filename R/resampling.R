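## fit + rotate in one step; x is a z-scored samples x analytes matrix
fitRotate <- function(x, groups, contrast, nLv = 2L, gridStep = 0.5) {
  rotateLvPlane(fitPlsda(x, groups, nLv = nLv), contrast = contrast,
                gridStep = gridStep)
}

## lean refit: rotated-LV1 loading vector only (sign resolved by the
## caller's alignment step)
rotatedLv1Loadings <- function(x, groups, contrast, nLv = 2L,
                               gridStep = 0.5) {
  g <- contrastFactor(groups, contrast)
  fit <- nipalsCore(x, stats::model.matrix(~ 0 + groups), nLv)
  if (nLv < 2L) return(fit$W[, 1])
  ang <- bestRotationAngle(fit$T[, 1:2, drop = FALSE], g, gridStep)$angle
  fit$W[, 1] * cos(ang) + fit$W[, 2] * sin(ang)
}

#' Leave-one-out stability envelope of the LV1 loadings
#'
#' Refits the full fit-and-rotate procedure with single samples excluded,
#' cycling through the samples until `nRefits` refits have been
#' accumulated (each sample is excluded `floor(nRefits/n)` or
#' `ceiling(nRefits/n)` times). Each refit's data are re-z-scored, its LV1
#' is sign-aligned to the full-data LV1 (flipped when the dot product is
#' negative), and the per-analyte mean and SD over all refits form the
#' envelope drawn as error bars on weighted-profile plots.
#'
#' Samples whose exclusion would leave a group with fewer than 2 members
#' are skipped with a warning and recorded.
#'
#' @param x z-scored [PanelExperiment-class] or samples x analytes matrix.
#' @param groups group labels (taken from `x` when a `PanelExperiment`).
#' @param contrast rotation contrast (see [rotateLvPlane()]).
#' @param nRefits total refits (default 1000).
#' @param nLv,gridStep passed to the fit/rotation.
#' @param reference optional LV1 loading vector to align against; defaults
#'   to the full-data rotated LV1.
#' @return A [LoadingEnvelope-class].
#' @export
looLoadingStability <- function(x, groups = NULL, contrast = "all",
                                nRefits = 1000L, nLv = 2L, gridStep = 0.5,
                                reference = NULL) {
  if (methods::is(x, "PanelExperiment")) {
    groups <- sampleGroups(x)
    x <- panelMatrix(x)
  }
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  n <- nrow(x)
  if (n < 4L) stopf("leave-one-out needs >= 4 samples")
  if (is.null(reference)) {
    reference <- rotatedLv1Loadings(zscoreMatrix(x), groups, contrast,
                                    nLv, gridStep)
    j <- which.max(abs(reference))        # same sign convention as the
    if (reference[j] < 0) reference <- -reference  # public rotated model
  }
  ## exclusions that would leave a group with < 2 samples are skipped
  sizes <- table(groups)
  eligible <- which(sizes[groups] > 2L)
  skipped <- rownames(x)[setdiff(seq_len(n), eligible)]
  if (length(skipped))
    warning(sprintf("excluding %s would leave a group with < 2 samples; %d refit slot(s) skipped",
                    paste(skipped, collapse = ", "), length(skipped)))
  if (!length(eligible)) stopf("no sample can be excluded")
  schedule <- rep_len(eligible, nRefits)
  counts <- tabulate(schedule, nbins = n)
  ## refits are deterministic per excluded sample: fit each once, weight by
  ## its number of appearances in the cycling schedule
  p <- ncol(x)
  flips <- 0L
  sumL <- numeric(p); sumL2 <- numeric(p)
  for (i in unique(schedule)) {
    L <- rotatedLv1Loadings(zscoreMatrix(x[-i, , drop = FALSE]),
                            droplevels(groups[-i]), contrast, nLv,
                            gridStep)
    if (sum(L * reference) < 0) { L <- -L; flips <- flips + counts[i] }
    sumL <- sumL + counts[i] * L
    sumL2 <- sumL2 + counts[i] * L^2
  }
  B <- sum(counts)
  mu <- sumL / B
  v <- pmax(0, (sumL2 - B * mu^2) / (B - 1))
  methods::new("LoadingEnvelope",
    envelope = data.frame(analyte = colnames(x), mean = mu, sd = sqrt(v)),
    nRefits = as.integer(B), alignmentFlips = as.integer(flips),
    skippedSamples = as.character(skipped), reference = reference)
}

#' Permutation test of PLS-DA group separation
#'
#' Builds an empirical null by shuffling the group labels (preserving group
#' sizes) and re-running the full pipeline — NIPALS fit plus LV-plane
#' rotation — on each shuffle, so the optimization step is included in the
#' null statistic and does not bias the test. The p-value uses the add-one
#' rule `p = (1 + #(null >= observed)) / (B + 1)`, which never returns 0.
#'
#' @param x z-scored [PanelExperiment-class] or samples x analytes matrix.
#' @param groups group labels.
#' @param contrast rotation contrast (see [rotateLvPlane()]).
#' @param B number of shuffles (>= 100).
#' @param seed RNG seed; identical seeds reproduce `nullStats` exactly.
#' @param nLv,gridStep passed to the fit/rotation.
#' @param withinBatch optional batch factor; when given, labels are
#'   shuffled only within batches.
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(x, groups = NULL, contrast = "all", B = 1000L,
                            seed = 1L, nLv = 2L, gridStep = 0.5,
                            withinBatch = NULL) {
  if (methods::is(x, "PanelExperiment")) {
    groups <- sampleGroups(x)
    if (isTRUE(withinBatch)) withinBatch <- sampleBatches(x)
    x <- panelMatrix(x)
  }
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  B <- as.integer(B)
  if (B < 100L) stopf("B must be >= 100 for a stable permutation p")
  statOf <- function(g)
    rotatedSeparation(x, g, contrast, nLv = nLv, gridStep = gridStep)
  observed <- statOf(groups)
  nullStats <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      g <- if (is.null(withinBatch)) sample(groups) else {
        out <- groups
        for (lv in split(seq_along(groups), withinBatch))
          out[lv] <- sample(groups[lv])
        out
      }
      statOf(g)
    }, numeric(1))
  })
  p <- (1 + sum(nullStats >= observed)) / (B + 1)
  methods::new("PermutationResult", observed = observed,
               nullStats = nullStats, pValue = p, B = B,
               seed = as.integer(seed))
}

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: observed %.4g, B = %d, p = %.4g\n",
              object@observed, object@B, object@pValue))
})

setMethod("show", "LoadingEnvelope", function(object) {
  cat(sprintf("LoadingEnvelope: %d analytes, %d refits (%d sign flips)\n",
              nrow(object@envelope), object@nRefits, object@alignmentFlips))
})

#' Write a loading envelope as tidy CSV
#'
#' @param env A [LoadingEnvelope-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnvelopeCsv <- function(env, path) {
  utils::write.csv(env@envelope, path, row.names = FALSE)
  invisible(path)
}

#' Write a permutation result as JSON
#'
#' @param perm A [PermutationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePermutationJson <- function(perm, path) {
  jsonlite::write_json(list(
    observed = perm@observed, null_stats = perm@nullStats,
    p_value = perm@pValue, B = perm@B, seed = perm@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
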