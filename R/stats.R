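#' One-way ANOVA
#'
#' Classical between/within decomposition via `stats::oneway.test` with
#' equal variances assumed. Degenerate input (zero within-group variance
#' with nonzero between) is reported at the numeric floor with a
#' `degenerate` flag rather than erroring, since multiplex panels
#' occasionally saturate.
#'
#' @param values numeric vector.
#' @param groups group labels (k >= 2, each n >= 2).
#' @return list with `F`, `dfBetween`, `dfWithin`, `p`, `groupMeans`,
#'   `degenerate`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stopf("need >= 2 groups")
  if (min(table(groups)) < 2L) stopf("each group needs >= 2 values")
  n <- length(values)
  mu <- tapply(values, groups, mean)
  ssw <- sum((values - mu[groups])^2)
  ssb <- sum(tabulate(groups) * (mu - mean(values))^2)
  if (ssw < .Machine$double.eps * max(1, ssb)) {
    if (ssb <= .Machine$double.eps) {
      return(list(F = 0, dfBetween = k - 1L, dfWithin = n - k, p = 1,
                  groupMeans = mu, degenerate = TRUE))
    }
    return(list(F = Inf, dfBetween = k - 1L, dfWithin = n - k,
                p = .Machine$double.xmin, groupMeans = mu,
                degenerate = TRUE))
  }
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), dfBetween = unname(ow$parameter[1]),
       dfWithin = unname(ow$parameter[2]), p = unname(ow$p.value),
       groupMeans = mu, degenerate = FALSE)
}

## pooled within-group variance and its df
pooledVariance <- function(values, groups) {
  mu <- tapply(values, groups, mean)
  df <- length(values) - nlevels(groups)
  list(s2 = sum((values - mu[groups])^2) / df, df = df, means = mu,
       n = table(groups))
}

#' Dunnett's many-to-one comparisons
#'
#' Compares every group to a designated reference, adjusting p-values by
#' the distribution of the maximum absolute statistic of the correlated
#' multivariate t implied by the design. The correlation structure is the
#' exact one-factor structure for (possibly unbalanced) group sizes,
#' \eqn{\rho_{ij} = \lambda_i \lambda_j} with
#' \eqn{\lambda_i = \sqrt{n_i/(n_i + n_0)}}, and the adjusted p is
#' evaluated by seeded Monte Carlo (shared chi-square denominator, one
#' common factor), with the Monte Carlo standard error reported.
#'
#' @param values numeric vector.
#' @param groups group labels (k >= 2; the k = 2 case is the single-comparison limit and reduces to the two-sided t test).
#' @param reference the control group label.
#' @param nDraws Monte Carlo draws (default 2e5).
#' @param seed RNG seed for the draws.
#' @return data.frame (`comparison`, `estimate`, `t`, `df`, `p`, `p_adj`,
#'   `mc_se`, `method`).
#' @export
dunnettTest <- function(values, groups, reference, nDraws = 2e5L,
                        seed = 1L) {
  groups <- droplevels(as.factor(groups))
  if (!reference %in% levels(groups))
    stopf("reference group '%s' not present", reference)
  if (nlevels(groups) < 2L) stopf("Dunnett needs >= 2 groups")
  pv <- pooledVariance(values, groups)
  others <- setdiff(levels(groups), reference)
  n0 <- pv$n[[reference]]
  ni <- vapply(others, function(g) pv$n[[g]], numeric(1))
  est <- pv$means[others] - pv$means[[reference]]
  se <- sqrt(pv$s2 * (1 / ni + 1 / n0))
  tstat <- est / se
  praw <- 2 * stats::pt(-abs(tstat), pv$df)
  lam <- sqrt(ni / (ni + n0))
  maxT <- withSeed(seed, {
    z0 <- stats::rnorm(nDraws)
    w <- sqrt(stats::rchisq(nDraws, pv$df) / pv$df)
    m <- rep(-Inf, nDraws)
    for (i in seq_along(others)) {
      zi <- stats::rnorm(nDraws)
      m <- pmax(m, abs(lam[i] * z0 + sqrt(1 - lam[i]^2) * zi))
    }
    m / w
  })
  padj <- vapply(abs(tstat), function(tt) mean(maxT >= tt), numeric(1))
  mcse <- sqrt(padj * (1 - padj) / nDraws)
  padj <- pmin(1, pmax(padj, praw))
  data.frame(comparison = paste(others, "-", reference),
             estimate = unname(est), t = unname(tstat), df = pv$df,
             p = unname(praw), p_adj = unname(padj), mc_se = unname(mcse),
             method = "dunnett")
}

#' Tukey's honestly-significant-difference comparisons
#'
#' All pairwise group comparisons with adjusted p-values from the
#' studentized range distribution (`stats::ptukey`, Tukey-Kramer form for
#' unbalanced sizes).
#'
#' @param values numeric vector.
#' @param groups group labels (k >= 2, each n >= 2; at k = 2 the adjusted p equals the raw t-test p).
#' @return data.frame (`comparison`, `estimate`, `t`, `df`, `p`, `p_adj`,
#'   `method`).
#' @export
tukeyHsd <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stopf("Tukey HSD needs >= 2 groups")
  if (min(table(groups)) < 2L) stopf("each group needs >= 2 values")
  pv <- pooledVariance(values, groups)
  cmb <- utils::combn(levels(groups), 2)
  res <- apply(cmb, 2, function(pr) {
    ni <- pv$n[[pr[1]]]; nj <- pv$n[[pr[2]]]
    est <- pv$means[[pr[2]]] - pv$means[[pr[1]]]
    se <- sqrt(pv$s2 * (1 / ni + 1 / nj))
    tt <- est / se
    c(est, tt)
  })
  tstat <- res[2, ]
  praw <- 2 * stats::pt(-abs(tstat), pv$df)
  padj <- stats::ptukey(sqrt(2) * abs(tstat), k, pv$df, lower.tail = FALSE)
  padj <- pmin(1, pmax(padj, praw))
  data.frame(comparison = paste(cmb[2, ], "-", cmb[1, ]),
             estimate = res[1, ], t = tstat, df = pv$df, p = praw,
             p_adj = padj, method = "tukey")
}

#' Two-sample t test (pooled or Welch)
#'
#' Pooled-variance t with `n1 + n2 - 2` degrees of freedom, or Welch's t
#' with Satterthwaite degrees of freedom. Zero variance in both groups with
#' equal means returns `t = 0, p = 1` (flagged degenerate) instead of
#' erroring.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch logical, use Welch's correction.
#' @return list with `t`, `df`, `p`, `estimate` (mean(a) - mean(b)),
#'   `degenerate`.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  if (stats::var(a) < .Machine$double.eps &&
      stats::var(b) < .Machine$double.eps) {
    d <- mean(a) - mean(b)
    df <- if (welch) NA_real_ else length(a) + length(b) - 2
    if (abs(d) < .Machine$double.eps)
      return(list(t = 0, df = df, p = 1, estimate = 0, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df = df, p = .Machine$double.xmin,
                estimate = d, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), estimate = unname(diff(rev(tt$estimate))),
       degenerate = FALSE)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: with raw p-values sorted ascending,
#' `p_adj(i) = 1 - (1 - p(i))^(m - i + 1)`, enforced monotone
#' non-decreasing and capped at 1.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
holmSidakAdjust <- function(p) {
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Control-normalized fold changes per animal
#'
#' Divides every measurement by the per-analyte mean of the control arm, so
#' the control group's per-analyte mean ratio is exactly 1 and stimulated
#' animals are expressed as fold change to control.
#'
#' @param stim,control samples x analytes matrices with matching analytes.
#' @return list of two fold-change matrices (`stim`, `control`).
#' @export
foldChangeTable <- function(stim, control) {
  if (!setequal(colnames(stim), colnames(control)))
    stopf("analyte sets differ: %s",
          paste(union(setdiff(colnames(stim), colnames(control)),
                      setdiff(colnames(control), colnames(stim))),
                collapse = ", "))
  stim <- stim[, colnames(control), drop = FALSE]
  ctrlMeans <- colMeans(control)
  list(stim = sweep(stim, 2, ctrlMeans, "/"),
       control = sweep(control, 2, ctrlMeans, "/"))
}

#' Fold-change contrast with Holm-Sidak correction
#'
#' Normalizes a stimulated arm and its control to the control's per-analyte
#' mean, runs a per-analyte two-sample t test between the arms on the
#' fold-change scale, and adjusts the analyte family with the Holm-Sidak
#' step-down method. `meanFoldChange` is the stimulated arm's mean ratio to
#' control (1 = no change).
#'
#' @param stim,control samples x analytes matrices (control n >= 2).
#' @param welch logical, Welch t tests.
#' @return data.frame (`analyte`, `meanFoldChange`, `estimate`, `t`, `df`,
#'   `p`, `p_adj`, `method`).
#' @export
foldChangeCompare <- function(stim, control, welch = FALSE) {
  if (nrow(control) < 2L) stopf("control group needs >= 2 samples")
  fc <- foldChangeTable(stim, control)
  res <- lapply(colnames(fc$stim), function(j) {
    tt <- twoSampleT(fc$stim[, j], fc$control[, j], welch = welch)
    data.frame(analyte = j, meanFoldChange = mean(fc$stim[, j]),
               estimate = tt$estimate, t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- holmSidakAdjust(out$p)
  out$method <- "holm_sidak"
  out
}
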