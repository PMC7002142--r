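test_that("linear-range exclusion drops exactly the flagged analytes", {
  ph <- emulateStudyDesigns(seed = 5)$phospho$panel
  st <- excludeOutOfRange(ph)
  expect_equal(nrow(st$panel), 11L)
  excl <- st$report@excludedAnalytes
  expect_equal(sort(excl$analyte),
               sort(c("c-Myc", "p-IkBa", "p-HSP27", "p-p38", "p-p53")))
  ## all-excluded panel errors
  vals <- matrix(1 + abs(rnorm(12)), 6, 2,
                 dimnames = list(paste0("S", 1:6), c("X", "Y")))
  bad <- PanelExperiment(vals,
    sampleData = data.frame(sample_id = rownames(vals),
                            group = rep(c("a", "b"), 3)),
    analyteData = data.frame(name = c("X", "Y"), panel = "p",
                             in_linear_range = FALSE))
  expect_error(excludeOutOfRange(bad), "all 2 analytes")
})

test_that("z-scoring standardizes, is idempotent, and rejects constants", {
  m <- cbind(A = c(1, 2, 3), B = c(10, 30, 20))
  rownames(m) <- paste0("S", 1:3)
  z <- plexsig:::zscoreMatrix(m)
  expect_equal(unname(z[, "A"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_lt(max(abs(plexsig:::zscoreMatrix(z) - z)), 1e-12)
  m2 <- cbind(m, C = c(5, 5, 5))
  expect_error(plexsig:::zscoreMatrix(m2), "constant analyte.*C")
  ## the panel wrapper flags the result
  pe <- quickPanel(matrix(abs(rnorm(12)) + 1, 6, 2,
                          dimnames = list(paste0("S", 1:6), c("A", "B"))),
                   rep(c("a", "b"), 3))
  expect_false(isZscored(pe))
  expect_true(isZscored(zscorePanel(pe)))
})

test_that("batch correction removes additive offsets exactly and keeps group effects", {
  ## noiseless additive construction: value = 10 + group effect + batch offset
  n <- 12
  g <- rep(c("a", "b"), each = 6)
  b <- rep(c("b1", "b2"), 6)
  ge <- cbind(A = ifelse(g == "a", 1, 0), B = 0, C = ifelse(g == "a", 0, 2))
  be <- cbind(A = ifelse(b == "b2", 0.5, 0), B = ifelse(b == "b2", -1, 0),
              C = 0)
  vals <- 10 + ge + be
  rownames(vals) <- paste0("S", 1:n)
  pe <- quickPanel(vals, g, batch = b)
  out <- removeBatchEffects(pe)
  corr <- panelMatrix(out$panel)
  ## the batch signal is removed up to a per-analyte constant (the grand
  ## batch mean is absorbed into the intercept, as in any additive fit)
  resid <- scale(corr, center = TRUE, scale = FALSE) -
    scale(10 + ge, center = TRUE, scale = FALSE)
  expect_lt(max(abs(resid)), 1e-8)
  expect_equal(mean(corr[g == "a", "A"]) - mean(corr[g == "b", "A"]), 1,
               tolerance = 1e-8)
  ## removed coefficients sum to zero over batches
  expect_lt(max(abs(colSums(out$report@batchCoefficients))), 1e-8)
})

test_that("batch correction matches limma on noisy unbalanced data", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 15
  g <- c(rep("a", 7), rep("b", 8))
  b <- c(rep("b1", 4), rep("b2", 3), rep("b1", 2), rep("b2", 6))
  vals <- matrix(rnorm(n * 5, mean = 5), n, 5,
                 dimnames = list(paste0("S", 1:n), paste0("A", 1:5)))
  vals[b == "b2", ] <- vals[b == "b2", ] + 0.8
  pe <- quickPanel(vals, g, batch = b)
  ours <- panelMatrix(removeBatchEffects(pe)$panel)
  ref <- t(limma::removeBatchEffect(t(vals), batch = b,
                                    design = model.matrix(~g)))
  expect_lt(max(abs(ours - ref)), 1e-8)
})

test_that("batch correction refuses confounded and single-batch layouts", {
  vals <- matrix(abs(rnorm(24)) + 5, 12, 2,
                 dimnames = list(paste0("S", 1:12), c("A", "B")))
  g <- rep(c("a", "b"), each = 6)
  expect_error(removeBatchEffects(quickPanel(vals, g, batch = g)),
               "confounded")
  expect_error(removeBatchEffects(quickPanel(vals, g,
                                             batch = rep("b1", 12))),
               ">= 2 batches")
})

test_that("outlier removal is targeted, idempotent, and guards sample counts", {
  set.seed(31)
  vals <- matrix(rnorm(24 * 10), 24, 10,
                 dimnames = list(paste0("S", 1:24), paste0("A", 1:10)))
  g <- rep(paste0("g", 1:4), each = 6)
  ## a sample sitting at the clean centroid is never removed
  vals[1, ] <- colMeans(vals[-1, ])
  res <- removeOutliers(quickPanel(vals, g, zscored = TRUE))
  expect_false("S1" %in% res$report@removedSamples$sample_id)
  ## idempotent: a second pass removes nothing
  res2 <- removeOutliers(res$panel)
  expect_equal(nrow(res2$report@removedSamples), 0L)
  ## parameter guards
  expect_error(removeOutliers(quickPanel(vals, g, zscored = TRUE),
                              confidence = 0.5),
               "confidence")
  small <- vals[1:2, ]
  expect_error(removeOutliers(quickPanel(small, g[1:2], zscored = TRUE),
                              nComponents = 2L),
               "more samples than components")
  ## beta cutoff is tighter than chisq at small n, never larger
  n <- 24; k <- 2
  expect_lt((n - 1)^2 / n * qbeta(0.995, k / 2, (n - k - 1) / 2),
            qchisq(0.995, k))
})

test_that("the full chain ends z-scored and merges its report", {
  fx <- emulateStudyDesigns(seed = 9)$phospho
  pp <- preprocessPanel(fx$panel)
  expect_true(isZscored(pp$panel))
  expect_equal(nrow(pp$panel), 11L)  # linear-range exclusions applied
  expect_equal(nrow(pp$report@excludedAnalytes), 5L)
  expect_false(is.null(pp$report@batchCoefficients))
  z <- panelMatrix(pp$panel)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  ## single-batch data: correction skipped with a message, not an error
  cy <- emulateStudyDesigns(seed = 9)$cytokine$panel
  expect_message(preprocessPanel(cy), "single batch")
})
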