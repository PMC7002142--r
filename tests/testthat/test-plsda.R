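test_that("rank-one data returns the generating direction as LV1", {
  set.seed(41)
  n <- 20; p <- 8
  tvec <- c(scale(rep(c(1, -1), each = n / 2) + rnorm(n, sd = 0.1)))
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  x <- tvec %*% t(w)
  colnames(x) <- paste0("A", 1:p); rownames(x) <- paste0("S", 1:n)
  g <- rep(c("a", "b"), each = n / 2)
  m <- fitPlsda(x, g, nLv = 1)
  expect_gt(abs(sum(m@loadings[, 1] * w)), 1 - 1e-10)
})

test_that("the LV1 weight matches the dominant singular vector of X'Y", {
  for (s in 1:10) {
    x <- randZ(18, 7, 400 + s)
    g <- factor(rep(c("a", "b", "c"), each = 6))
    Y <- model.matrix(~ 0 + g)
    m <- fitPlsda(x, g, nLv = 2)
    u1 <- svd(crossprod(x, Y))$u[, 1]
    expect_gt(abs(sum(m@loadings[, 1] * u1)), 1 - 1e-8)
  }
})

test_that("duplicated analytes share the LV1 loading symmetrically", {
  x <- randZ(18, 6, 43)
  x2 <- cbind(x, x[, 1])
  colnames(x2) <- c(colnames(x), "A01dup")
  g <- rep(c("a", "b", "c"), each = 6)
  m <- fitPlsda(x2, g, nLv = 1)
  expect_equal(m@loadings["A01", 1], m@loadings["A01dup", 1],
               tolerance = 1e-10)
})

test_that("scores are orthogonal and loadings orthonormal", {
  x <- randZ(24, 12, 47)
  g <- rep(paste0("g", 1:4), each = 6)
  m <- fitPlsda(x, g, nLv = 3)
  G <- crossprod(m@scores)
  offdiag <- G[upper.tri(G)]
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_lt(max(abs(crossprod(m@loadings) - diag(3))), 1e-8)
  ## sign convention: largest-|loading| entry is positive
  for (a in 1:3) expect_gt(m@loadings[which.max(abs(m@loadings[, a])), a], 0)
})

test_that("fitPlsda enforces its preconditions", {
  x <- randZ(12, 5, 53)
  g <- rep(c("a", "b"), each = 6)
  expect_error(fitPlsda(x, g, nLv = 6), "exceeds")
  expect_error(fitPlsda(x, rep("a", 12)), ">= 2 groups")
  pe <- quickPanel(exp(x), g)  # raw, not z-scored
  expect_error(fitPlsda(pe), "z-scored")
})

test_that("rotation is an isometry of the LV plane and never hurts separation", {
  for (s in 1:5) {
    x <- randZ(24, 10, 500 + s)
    g <- rep(paste0("g", 1:4), each = 6)
    m0 <- fitPlsda(x, g, nLv = 2)
    m1 <- rotateLvPlane(m0)
    ## plane-invariants preserved
    expect_equal(sum(m1@scores[, 1:2]^2), sum(m0@scores[, 1:2]^2),
                 tolerance = 1e-10)
    expect_lt(max(abs(crossprod(m1@loadings) - diag(2))), 1e-8)
    ## rotated-LV1 separation >= the unrotated one (angle 0 is a candidate)
    sep0 <- plexsig:::separationStat(m0@scores[, 1], g)$statistic
    expect_gte(m1@separation[1], sep0 - 1e-10)
  }
})

test_that("scoreSeparation matches the brute-force F ratio", {
  x <- randZ(24, 8, 61)
  g <- factor(rep(paste0("g", 1:4), each = 6))
  m <- rotateLvPlane(fitPlsda(x, g))
  s <- m@scores[, 1]
  mu <- tapply(s, g, mean)
  ssb <- sum(6 * (mu - mean(s))^2); ssw <- sum((s - mu[g])^2)
  expect_equal(scoreSeparation(m)@statistic, (ssb / 3) / (ssw / 20),
               tolerance = 1e-12)
  ## one-vs-rest contrast, brute force
  g2 <- factor(ifelse(g == "g1", "g1", "rest"))
  mu2 <- tapply(s, g2, mean)
  ssb2 <- sum(table(g2) * (mu2 - mean(s))^2)
  ssw2 <- sum((s - mu2[g2])^2)
  expect_equal(scoreSeparation(m, contrast = "g1")@statistic,
               ssb2 / (ssw2 / 22), tolerance = 1e-12)
  expect_error(scoreSeparation(m, contrast = "zz"), "not present")
})

test_that("perfect separation is reported as capped Inf", {
  s <- plexsig:::separationStat(c(0, 0, 0, 1, 1, 1),
                                rep(c("a", "b"), each = 3))
  expect_identical(s$statistic, Inf)
  expect_true(s$capped)
})

test_that("topLoadings ranks with lexicographic tie-breaks", {
  W <- matrix(rep(0.5, 4), 4, 1,
              dimnames = list(c("B", "D", "A", "C"), "LV1"))
  m <- handModel(W, matrix(rnorm(4), 4, 1), rep(c("x", "y"), 2))
  tl <- topLoadings(m, k = 4)
  expect_identical(tl$analyte, c("A", "B", "C", "D"))
  expect_error(topLoadings(m, k = 9), "exceeds")
  ## absolute ranking picks large negative loadings
  W2 <- cbind(LV1 = c(0.9, -sqrt(1 - 0.81 - 0.01), 0.1, 0))
  rownames(W2) <- c("P", "N", "S", "Z")
  m2 <- handModel(W2, matrix(rnorm(4), 4, 1), rep(c("x", "y"), 2))
  expect_identical(topLoadings(m2, k = 2, absolute = TRUE)$analyte[1:2],
                   c("P", "N"))
})
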