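test_that("one-way ANOVA matches the sum-of-squares oracle and handles edges", {
  set.seed(101)
  v <- rnorm(24); g <- factor(rep(paste0("g", 1:4), each = 6))
  av <- oneWayAnova(v, g)
  expect_equal(av$dfBetween, 3); expect_equal(av$dfWithin, 20)
  mu <- tapply(v, g, mean)
  ssb <- sum(6 * (mu - mean(v))^2); ssw <- sum((v - mu[g])^2)
  expect_equal(av$F, (ssb / 3) / (ssw / 20), tolerance = 1e-10)
  expect_equal(av$p, pf(av$F, 3, 20, lower.tail = FALSE), tolerance = 1e-12)
  ## F = t^2 at k = 2
  v2 <- rnorm(12); g2 <- rep(c("a", "b"), each = 6)
  av2 <- oneWayAnova(v2, g2)
  tt <- twoSampleT(v2[g2 == "a"], v2[g2 == "b"])
  expect_equal(av2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(av2$p, tt$p, tolerance = 1e-12)
  ## degenerate: constant data
  avc <- oneWayAnova(rep(1, 12), g2)
  expect_equal(avc$F, 0); expect_equal(avc$p, 1); expect_true(avc$degenerate)
  expect_error(oneWayAnova(rnorm(3), c("a", "a", "b")), ">= 2 values")
})

test_that("Dunnett reduces to the t test in the single-comparison limit", {
  set.seed(103)
  v <- rnorm(14); g <- rep(c("ctrl", "stim"), each = 7)
  v[g == "stim"] <- v[g == "stim"] + 1
  d <- dunnettTest(v, g, "ctrl", nDraws = 2e5, seed = 2)
  tt <- twoSampleT(v[g == "stim"], v[g == "ctrl"])
  expect_equal(d$p, tt$p, tolerance = 1e-12)
  ## 3-SE bound: a 2-SE check on a Monte Carlo estimate fails ~2% of the
  ## time by construction; the tighter spec-level check lives in the
  ## acceptance suite
  expect_lt(abs(d$p_adj - tt$p), 3 * d$mc_se + 1e-12)
  expect_error(dunnettTest(v, g, "nope"), "not present")
})

test_that("Dunnett matches the mvtnorm multivariate-t oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(107)
  v <- rnorm(24); g <- factor(rep(paste0("g", 1:4), each = 6))
  v[g == "g2"] <- v[g == "g2"] + 1
  d <- dunnettTest(v, g, "g1", nDraws = 5e5, seed = 3)
  lam <- sqrt(6 / 12)
  corr <- diag(3) * (1 - lam^2) + lam^2
  oracle <- vapply(abs(d$t), function(tt)
    1 - mvtnorm::pmvt(lower = rep(-tt, 3), upper = rep(tt, 3),
                      corr = corr, df = 20,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1],
    numeric(1))
  expect_lt(max(abs(d$p_adj - oracle)), 3 * max(d$mc_se) + 1e-4)
})

test_that("Tukey matches TukeyHSD and its k = 2 identity", {
  set.seed(109)
  v <- rnorm(24); g <- factor(rep(paste0("g", 1:4), each = 6))
  tk <- tukeyHsd(v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ g))$g
  refP <- ref[gsub(" ", "", tk$comparison), "p adj"]
  expect_lt(max(abs(tk$p_adj - refP)), 1e-8)
  expect_equal(nrow(tk), 6L)
  ## k = 2: the studentized-range tail equals the two-sided t tail
  v2 <- rnorm(10); g2 <- rep(c("a", "b"), each = 5)
  tk2 <- tukeyHsd(v2, g2)
  ## ptukey is accurate to ~1e-8, not machine precision
  expect_equal(tk2$p_adj, tk2$p, tolerance = 1e-7)
})

test_that("two-sample t covers pooled, Welch and degenerate cases", {
  set.seed(113)
  a <- rnorm(12); b <- rnorm(6, sd = 3)
  tp <- twoSampleT(a, b)
  expect_equal(tp$df, 16)
  tw <- twoSampleT(a, b, welch = TRUE)
  sa <- var(a) / 12; sb <- var(b) / 6
  dfSat <- (sa + sb)^2 / (sa^2 / 11 + sb^2 / 5)
  expect_equal(tw$df, dfSat, tolerance = 1e-10)
  expect_equal(tw$t, (mean(a) - mean(b)) / sqrt(sa + sb), tolerance = 1e-10)
  dg <- twoSampleT(rep(2, 4), rep(2, 5))
  expect_true(dg$degenerate); expect_equal(dg$p, 1)
  expect_error(twoSampleT(1, rnorm(4)), ">= 2 values")
})

test_that("Holm-Sidak adjustment matches hand computation", {
  expect_equal(holmSidakAdjust(0.04), 0.04)
  p <- c(0.01, 0.04, 0.03, 0.005)
  ## sorted: 0.005, 0.01, 0.03, 0.04 -> 1-(1-p)^(4,3,2,1), cummax
  byHand <- c(1 - (1 - 0.005)^4, 1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 0.04)
  byHand <- cummax(byHand)
  expect_equal(holmSidakAdjust(p), byHand[c(2, 4, 3, 1)], tolerance = 1e-12)
  set.seed(117)
  praw <- runif(20)
  adj <- holmSidakAdjust(praw)
  expect_true(all(adj >= praw - 1e-15))
  expect_true(all(adj <= 1 & adj >= 0))
  expect_error(holmSidakAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold-change tables normalize to the control mean", {
  set.seed(127)
  ctrl <- matrix(abs(rnorm(18)) + 1, 6, 3,
                 dimnames = list(paste0("C", 1:6), c("X", "Y", "Z")))
  stim <- matrix(abs(rnorm(18)) + 1, 6, 3,
                 dimnames = list(paste0("T", 1:6), c("X", "Y", "Z")))
  fc <- foldChangeTable(stim, ctrl)
  expect_equal(unname(colMeans(fc$control)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(fc$stim[, "X"], stim[, "X"] / mean(ctrl[, "X"]),
               tolerance = 1e-12)
  bad <- stim; colnames(bad) <- c("X", "Y", "W")
  expect_error(foldChangeTable(bad, ctrl), "analyte sets differ.*[WZ]")
  ## control against itself: nothing significant
  res <- foldChangeCompare(ctrl, ctrl)
  expect_true(all(res$p_adj == 1))
  expect_equal(res$meanFoldChange, rep(1, 3), tolerance = 1e-12)
})

test_that("foldChangeCompare detects a planted shift and adjusts the family", {
  set.seed(131)
  ctrl <- matrix(exp(rnorm(30, sd = 0.1)), 6, 5,
                 dimnames = list(paste0("C", 1:6), paste0("A", 1:5)))
  stim <- matrix(exp(rnorm(30, sd = 0.1)), 6, 5,
                 dimnames = list(paste0("T", 1:6), paste0("A", 1:5)))
  stim[, "A1"] <- stim[, "A1"] * 4
  res <- foldChangeCompare(stim, ctrl)
  expect_lt(res$p_adj[res$analyte == "A1"], 0.05)
  expect_gt(res$meanFoldChange[res$analyte == "A1"], 2)
  expect_true(all(res$p_adj >= res$p - 1e-15))
})
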