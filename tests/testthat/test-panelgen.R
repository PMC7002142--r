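test_that("design and effects constructors validate their inputs", {
  d <- nullDesign(1)
  expect_error(PanelEffects(d, groupShifts = list(zz = c(A01 = 1))),
               "unknown group")
  expect_error(PanelEffects(d, groupShifts = list(g1 = c(nope = 1))),
               "unknown analyte")
  expect_error(PanelEffects(d, batchOffsets = list(b9 = c(A01 = 1))),
               "unknown batch")
  expect_error(PanelEffects(d, blocks = list(list(analytes = c("A01", "xx"),
                                                  loading = 0.5))),
               "unknown analyte")
  ## character analyte shorthand is wrapped into a roster
  d2 <- PanelDesign(c("a", "b"), 3, c("X", "Y"))
  expect_identical(d2@analytes$name, c("X", "Y"))
  expect_true(all(d2@analytes$in_linear_range))
})

test_that("generation is deterministic for a fixed seed, on disk too", {
  d <- nullDesign(42, nBatches = 2L)
  e <- PanelEffects(d, groupShifts = list(g1 = c(A01 = 0.5)),
                    batchOffsets = "random", outlierFraction = 0.1)
  g1 <- generatePanel(d, e)
  g2 <- generatePanel(d, e)
  expect_identical(panelMatrix(g1$panel), panelMatrix(g2$panel))
  expect_identical(g1$truth@outlierSamples, g2$truth@outlierSamples)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePanelCsv(g1$panel, f1)
  writePanelCsv(g2$panel, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("round-robin batches never confound batch with group", {
  d <- nullDesign(7, nBatches = 2L)
  g <- generatePanel(d)
  tab <- table(sampleGroups(g$panel), sampleBatches(g$panel))
  expect_true(all(tab == 3L))  # 6 per group split evenly over 2 batches
})

test_that("emulated study designs have the reported shapes", {
  fx <- emulateStudyDesigns(seed = 3)
  cy <- fx$cytokine$panel
  expect_equal(dim(panelMatrix(cy)), c(24L, 32L))
  expect_equal(sort(levels(sampleGroups(cy))),
               sort(c("40Hz", "20Hz", "random", "light")))
  expect_true(all(inLinearRange(cy)))
  ph <- fx$phospho$panel
  expect_equal(ncol(ph), 17L + 12L + 6L + 3L * 6L)  # 53 samples
  expect_equal(nrow(ph), 16L)
  usable <- inLinearRange(ph)
  expect_equal(sum(usable[analytePanels(ph) == "nfkb"]), 4L)
  expect_equal(sum(usable[analytePanels(ph) == "mapk"]), 7L)
  expect_equal(sum(usable), 11L)
  expect_equal(choose(sum(usable), 2), 55)
  expect_gte(nlevels(sampleBatches(ph)), 2L)
})

test_that("null generation carries no spurious group signal", {
  ## per-analyte two-group t tests on log values across 100 null replicates
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    d <- nullDesign(1000 + s, nGroups = 2L, n = 6L, p = 8L)
    m <- log(panelMatrix(generatePanel(d)$panel))
    g <- rep(c("g1", "g2"), each = 6)
    p <- apply(m, 2, function(v)
      stats::t.test(v[g == "g1"], v[g == "g2"], var.equal = TRUE)$p.value)
    hits <- hits + sum(p < 0.01)
    total <- total + length(p)
  }
  expect_lte(hits / total, 0.02)
})

test_that("a planted shift is recovered at its planted size", {
  d <- nullDesign(11, nGroups = 2L, n = 50L, p = 4L)
  e <- PanelEffects(d, groupShifts = list(g1 = c(A01 = 1)))
  m <- log(panelMatrix(generatePanel(d, e)$panel))
  g <- rep(c("g1", "g2"), each = 50)
  diffA1 <- mean(m[g == "g1", "A01"]) - mean(m[g == "g2", "A01"])
  se <- sqrt(2 * 0.3^2 / 50)
  expect_lt(abs(diffA1 - 1), 4 * se)
  diffA2 <- mean(m[g == "g1", "A02"]) - mean(m[g == "g2", "A02"])
  expect_lt(abs(diffA2), 4 * se)
})

test_that("planted outliers sit far outside the clean cloud", {
  d <- nullDesign(13)
  e <- PanelEffects(d, outlierFraction = 1 / 12)  # 2 of 24 samples
  g <- generatePanel(d, e)
  m <- log(panelMatrix(g$panel))
  out <- rownames(m) %in% g$truth@outlierSamples
  expect_equal(sum(out), 2L)
  ## outliers shift every analyte by 6 * noiseSd = 1.8 on the log scale;
  ## the per-sample mean deviation from the clean centroid detects that
  centroid <- colMeans(m[!out, , drop = FALSE])
  dev <- rowMeans(sweep(m, 2, centroid))
  expect_true(all(dev[out] > 1))
  expect_true(all(abs(dev[!out]) < 0.5))
})

test_that("ground truth records shifts, blocks and outliers faithfully", {
  d <- nullDesign(17)
  e <- PanelEffects(d,
    groupShifts = list(g2 = c(A03 = 0.4, A04 = 0.4)),
    blocks = list(list(analytes = c("A05", "A06", "A07"), loading = 0.7)))
  tr <- generatePanel(d, e)$truth
  expect_identical(tr@discriminatingAnalytes$g2, c("A03", "A04"))
  expect_identical(tr@discriminatingAnalytes$g1, character(0))
  expect_equal(nrow(tr@correlatedPairs), 3L)  # C(3, 2)
  expect_identical(tr@outlierSamples, character(0))
})
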