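## -------- internal: separation statistic --------------------------------
## Between/within mean-square ratio of a 1-D score vector under a contrast:
## "all" keeps the full grouping; a group label collapses to that group vs
## the pooled rest. Returns list(statistic, perGroupMeans, capped).
separationStat <- function(scores, groups, contrast = "all") {
  groups <- droplevels(as.factor(groups))
  perGroup <- c(tapply(scores, groups, mean))
  g <- if (identical(contrast, "all")) groups else {
    if (!contrast %in% levels(groups))
      stopf("contrast group '%s' not present", contrast)
    factor(ifelse(groups == contrast, contrast, "rest"))
  }
  if (min(table(g)) < 2L)
    stopf("every contrast group needs >= 2 samples")
  k <- nlevels(g)
  n <- length(scores)
  gm <- mean(scores)
  mu <- tapply(scores, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (mu - gm)^2)
  ssw <- sum((scores - mu[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (msw < .Machine$double.eps * max(1, msb)) {
    list(statistic = if (msb > 0) Inf else 0,
         perGroupMeans = perGroup, capped = msb > 0)
  } else {
    list(statistic = msb / msw, perGroupMeans = perGroup, capped = FALSE)
  }
}

## vectorized separation ratio for many candidate axes at once:
## S is n x m (each column a candidate 1-D score vector)
separationStatMany <- function(S, g) {
  k <- nlevels(g)
  n <- nrow(S)
  ns <- tabulate(g, nbins = k)
  mu <- rowsum(S, as.integer(g), reorder = TRUE) / ns  # k x m group means
  gm <- colMeans(S)
  sst <- colSums(S^2) - n * gm^2
  ssb <- colSums(ns * mu^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  out <- msb / msw
  out[msw < .Machine$double.eps * pmax(1, msb)] <- Inf
  out[msb <= 0 & msw <= .Machine$double.eps] <- 0
  out
}

contrastFactor <- function(groups, contrast) {
  groups <- droplevels(as.factor(groups))
  if (identical(contrast, "all")) groups
  else factor(ifelse(groups == contrast, contrast, "rest"))
}

## -------- internal lean cores (no S4 construction) ----------------------
## NIPALS PLS2: returns unit-norm weight matrix W (p x nLv) and the
## orthogonal NIPALS score matrix T (n x nLv); sign convention applied.
nipalsCore <- function(x, Y, nLv, tol = 1e-10, maxIter = 50000L) {
  n <- nrow(x); p <- ncol(x)
  Xd <- x; Yd <- Y
  W <- matrix(0, p, nLv)
  Tm <- matrix(0, n, nLv)
  for (a in seq_len(nLv)) {
    M <- crossprod(Xd, Yd)                       # p x k
    w <- M[, which.max(colSums(M^2))]
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stopf("degenerate component %d: X'Y vanished after deflation", a)
    w <- w / nw
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      Aw <- M %*% crossprod(M, w)                # (X'Y)(Y'X) w
      lam <- sum(w * Aw)
      ## eigen-residual criterion: near-ties of the top eigenvalues slow
      ## the directional convergence, but any vector in the tied dominant
      ## subspace is a dominant direction and the residual detects that
      resid <- sqrt(sum((Aw - lam * w)^2)) / max(lam, .Machine$double.eps)
      wNew <- Aw / sqrt(sum(Aw^2))
      if (sum(wNew * w) < 0) wNew <- -wNew
      delta <- sqrt(sum((wNew - w)^2))
      w <- wNew
      if (min(resid, delta) < tol) { conv <- TRUE; break }
    }
    if (!conv)
      stopf("power iteration did not converge for component %d (%d iterations, tolerance %g)",
            a, maxIter, tol)
    tvec <- Xd %*% w
    tt <- sum(tvec^2)
    pvec <- crossprod(Xd, tvec) / tt
    qvec <- crossprod(Yd, tvec) / tt
    Xd <- Xd - tvec %*% t(pvec)
    Yd <- Yd - tvec %*% t(qvec)
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; tvec <- -tvec }
    W[, a] <- w
    Tm[, a] <- tvec
  }
  list(W = W, T = Tm)
}

## rotation-grid cache (cos/sin rows per grid step)
.gridCache <- new.env(parent = emptyenv())
rotationGrid <- function(gridStep) {
  key <- format(gridStep, digits = 12)
  if (is.null(.gridCache[[key]])) {
    theta <- seq(0, pi, by = gridStep * pi / 180)
    theta <- theta[theta < pi]
    .gridCache[[key]] <- list(theta = theta,
                              A = rbind(cos(theta), sin(theta)))
  }
  .gridCache[[key]]
}

## best planar rotation of the (LV1, LV2) score pair for a contrast factor
## g: grid search + local golden-section refinement. Returns angle + value.
bestRotationAngle <- function(Tm, g, gridStep = 0.5, refine = TRUE) {
  gr <- rotationGrid(gridStep)
  stats <- separationStatMany(Tm %*% gr$A, g)
  iBest <- which.max(stats)
  best <- gr$theta[iBest]
  value <- stats[iBest]
  if (refine && is.finite(value)) {
    step <- gridStep * pi / 180
    obj <- function(th)
      separationStatMany(Tm %*% rbind(cos(th), sin(th)), g)
    opt <- stats::optimize(obj, interval = c(best - step, best + step),
                           maximum = TRUE, tol = 1e-10)
    if (opt$objective >= value) { best <- opt$maximum; value <- opt$objective }
  }
  list(angle = best %% pi, value = value)
}

## rotated-LV1 separation statistic of a fit, without building S4 objects;
## the permutation-test statistic
rotatedSeparation <- function(x, groups, contrast, nLv = 2L,
                              gridStep = 0.5) {
  g <- contrastFactor(groups, contrast)
  Y <- stats::model.matrix(~ 0 + groups)
  fit <- nipalsCore(x, Y, nLv)
  if (nLv < 2L)
    return(separationStatMany(fit$T[, 1, drop = FALSE], g))
  bestRotationAngle(fit$T[, 1:2, drop = FALSE], g, gridStep)$value
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least-squares discriminant analysis: group membership is one-hot
#' encoded as the response block Y, and components are extracted by the
#' NIPALS algorithm. Per component, the weight vector is the dominant
#' eigenvector of \eqn{X'YY'X} (found by power iteration to tolerance
#' `tol`), the score is \eqn{t = Xw}, and X and Y are deflated by the
#' rank-one regression on \eqn{t}. The PLS sign indeterminacy is resolved by
#' flipping each component so its largest-magnitude loading is positive,
#' making the fit deterministic for fixed input.
#'
#' @param x z-scored [PanelExperiment-class], or a numeric samples x
#'   analytes matrix with column means ~0 (z-scored).
#' @param groups sample group labels (taken from `x` when it is a
#'   `PanelExperiment`).
#' @param nLv number of latent variables (<= min(n_samples - 1,
#'   n_analytes)); default 2, the interpreted LV1/LV2 plane.
#' @param tol power-iteration convergence tolerance.
#' @param maxIter maximum power iterations per component.
#' @return A [PlsdaModel-class] with `rotationAngle = 0`.
#' @seealso [rotateLvPlane()], [scoreSeparation()], [topLoadings()]
#' @export
fitPlsda <- function(x, groups = NULL, nLv = 2L, tol = 1e-10,
                     maxIter = 50000L) {
  if (methods::is(x, "PanelExperiment")) {
    if (!isZscored(x)) stopf("fitPlsda requires a z-scored panel")
    groups <- sampleGroups(x)
    x <- panelMatrix(x)
  }
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stopf("need >= 2 groups")
  n <- nrow(x); p <- ncol(x)
  nLv <- as.integer(nLv)
  if (nLv > min(n - 1L, p))
    stopf("nLv = %d exceeds min(n_samples - 1, n_analytes) = %d",
          nLv, min(n - 1L, p))
  Y <- stats::model.matrix(~ 0 + groups)
  fit <- nipalsCore(x, Y, nLv, tol = tol, maxIter = maxIter)
  W <- fit$W
  Tm <- fit$T
  dimnames(W) <- list(colnames(x), paste0("LV", seq_len(nLv)))
  dimnames(Tm) <- list(rownames(x), paste0("LV", seq_len(nLv)))
  methods::new("PlsdaModel", loadings = W, scores = Tm, groups = groups,
               nLv = nLv, rotationAngle = 0,
               contrast = NA_character_,
               separation = rep(NA_real_, nLv),
               separationCapped = rep(FALSE, nLv))
}

#' Rotate the LV1-LV2 plane to the best-separating axis
#'
#' Applies an orthogonal (planar) rotation jointly to the (LV1, LV2)
#' loadings and scores, choosing the angle that maximizes the
#' between/within variance ratio of the rotated-LV1 scores under
#' `contrast`. The angle is found by a grid search over \eqn{[0, \pi)}
#' (default step 0.5 degrees) followed by golden-section refinement around
#' the best grid point. Rotation preserves the orthonormality of the
#' loading pair and the total score variance captured by the plane.
#'
#' @param model A fitted [PlsdaModel-class] with >= 2 LVs.
#' @param contrast `"all"` (multi-group separation) or a group label
#'   (that group versus the pooled rest).
#' @param gridStep grid resolution in degrees.
#' @param refine logical, golden-section refinement of the best grid angle.
#' @return The rotated [PlsdaModel-class] (`rotationAngle`, `separation`
#'   and `contrast` filled in; sign convention re-applied per LV).
#' @export
rotateLvPlane <- function(model, contrast = "all", gridStep = 0.5,
                          refine = TRUE) {
  if (model@nLv < 2L) stopf("rotation needs >= 2 latent variables")
  g <- contrastFactor(model@groups, contrast)
  Tm <- model@scores[, 1:2, drop = FALSE]
  best <- bestRotationAngle(Tm, g, gridStep = gridStep,
                            refine = refine)$angle
  co <- cos(best); si <- sin(best)
  R <- matrix(c(co, si, -si, co), 2, 2)   # columns: new LV1, new LV2
  W <- model@loadings
  Tall <- model@scores
  W[, 1:2] <- W[, 1:2, drop = FALSE] %*% R
  Tall[, 1:2] <- Tall[, 1:2, drop = FALSE] %*% R
  for (a in 1:2) {                        # re-apply sign convention
    j <- which.max(abs(W[, a]))
    if (W[j, a] < 0) { W[, a] <- -W[, a]; Tall[, a] <- -Tall[, a] }
  }
  sep <- vapply(seq_len(model@nLv), function(a)
    separationStat(Tall[, a], model@groups, contrast)$statistic, numeric(1))
  methods::new("PlsdaModel", loadings = W, scores = Tall,
               groups = model@groups, nLv = model@nLv,
               rotationAngle = best, contrast = contrast,
               separation = sep, separationCapped = !is.finite(sep) & sep > 0)
}

#' Group separation of a latent-variable axis
#'
#' Between/within variance (mean-square) ratio of the scores on one LV
#' under a contrast; this is the statistic that both the plane rotation and
#' the permutation test optimize/resample, and it feeds the univariate
#' ANOVA on LV1 scores.
#'
#' @param model A [PlsdaModel-class].
#' @param contrast `"all"` or a group label (one-vs-rest).
#' @param lv which latent variable (default 1).
#' @return A [GroupSeparation-class]. Perfect separation (zero
#'   within-group variance) is reported as `statistic = Inf` with
#'   `capped = TRUE`.
#' @export
scoreSeparation <- function(model, contrast = "all", lv = 1L) {
  s <- separationStat(model@scores[, lv], model@groups, contrast)
  methods::new("GroupSeparation", statistic = s$statistic,
               perGroupMeans = s$perGroupMeans, capped = s$capped,
               contrast = contrast)
}

#' Rank analytes by their LV loading
#'
#' Analytes sorted by signed (or absolute) loading on an LV, descending;
#' ties are broken lexicographically by analyte name.
#'
#' @param model A [PlsdaModel-class].
#' @param k how many analytes to return.
#' @param lv which latent variable (default 1).
#' @param absolute rank by |loading| instead of signed loading.
#' @return data.frame (`analyte`, `loading`, `rank`).
#' @export
topLoadings <- function(model, k = nrow(model@loadings), lv = 1L,
                        absolute = FALSE) {
  w <- model@loadings[, lv]
  if (k > length(w)) stopf("k = %d exceeds %d analytes", k, length(w))
  key <- if (absolute) abs(w) else w
  ord <- order(-key, names(w))
  data.frame(analyte = names(w)[ord][seq_len(k)],
             loading = unname(w[ord][seq_len(k)]),
             rank = seq_len(k))
}

setMethod("show", "PlsdaModel", function(object) {
  cat(sprintf("PlsdaModel: %d analytes, %d samples, %d LVs\n",
              nrow(object@loadings), nrow(object@scores), object@nLv))
  if (!is.na(object@contrast)) {
    cat(sprintf("  rotated %.2f deg, contrast '%s', LV1 separation %.3g%s\n",
                object@rotationAngle * 180 / pi, object@contrast,
                object@separation[1],
                if (object@separationCapped[1]) " (capped)" else ""))
  }
  top <- topLoadings(object, k = min(4L, nrow(object@loadings)))
  cat("  top LV1 loadings:",
      paste(sprintf("%s (%.2f)", top$analyte, top$loading),
            collapse = ", "), "\n")
})

setMethod("show", "GroupSeparation", function(object) {
  cat(sprintf("GroupSeparation [%s]: %.4g%s\n", object@contrast,
              object@statistic, if (object@capped) " (capped)" else ""))
})

#' Serialize a PlsdaModel to JSON
#'
#' @param model A [PlsdaModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePlsdaJson <- function(model, path) {
  jsonlite::write_json(list(
    loadings = as.data.frame(model@loadings),
    analytes = rownames(model@loadings),
    scores = as.data.frame(model@scores),
    samples = rownames(model@scores),
    groups = as.character(model@groups),
    n_lv = model@nLv,
    rotation_angle = model@rotationAngle,
    contrast = model@contrast,
    separation = model@separation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
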