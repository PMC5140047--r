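test_that("BAF folding is symmetric about 0.5 and rejects out-of-range input", {
  expect_equal(foldBaf(c(0.2, 0.8)), c(0.2, 0.2))
  expect_equal(foldBaf(0.5), 0.5)
  expect_equal(foldBaf(c(1 / 3, 2 / 3, 0.5)), c(1 / 3, 1 / 3, 0.5))
  expect_error(foldBaf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("EM recovers noise-free peaks and agrees with a grid-search likelihood oracle", {
  x <- rep(c(1 / 3, 2 / 3), 100)
  fit <- fitBafPeaks(x)
  expect_true(fit$ok)
  expect_equal(fit$mu1, 1 / 3, tolerance = 1e-3)
  expect_equal(fit$mu2, 2 / 3, tolerance = 1e-3)
  expect_equal(fit$mu1, oracleGridPeak(x), tolerance = 1e-3)
  expect_false(fit$degenerate)
})

test_that("EM on a peakless CN2 segment flags the degenerate single-peak case", {
  fit <- fitBafPeaks(rep(0.5, 200))
  expect_true(fit$ok)
  expect_equal(fit$mu1, 0.5, tolerance = 1e-6)
  expect_true(fit$degenerate)
})

test_that("EM recovers peaks (0.4, 0.6) within 0.01 from 500 noisy draws and its log-likelihood never decreases", {
  set.seed(77)
  x <- ifelse(runif(500) < 0.5, rnorm(500, 0.4, 0.03), rnorm(500, 0.6, 0.03))
  x <- pmin(pmax(x, 0), 1)
  fit <- fitBafPeaks(x)
  expect_lt(abs(fit$mu1 - 0.4), 0.01)
  expect_lt(abs(fit$mu2 - 0.6), 0.01)
  expect_true(all(diff(fit$logLik) >= -1e-8))
  expect_equal(fit$mu1, oracleGridPeak(x), tolerance = 5e-3)
})

test_that("segments with too few probes are left unassigned rather than erroring", {
  fit <- fitBafPeaks(c(0.3, 0.7), minProbes = 50L)
  expect_false(fit$ok)
  expect_identical(fit$reason, "too_few_probes")
})

test_that("peak positions invert to cell fractions and round-trip exactly", {
  expect_equal(cellFractionFromPeaks(1 / 3, 2 / 3, "CN1"), 0.5,
               tolerance = 1e-12)
  expect_equal(cellFractionFromPeaks(0.4, 0.6, "LOH"), 0.2,
               tolerance = 1e-12)
  expect_equal(cellFractionFromPeaks(0.5, 0.5, "CN1"), 0)
  expect_error(cellFractionFromPeaks(0.3, 0.7, "AMP"))
  for (c in seq(0, 1, length.out = 101)) {
    expect_equal(cellFractionFromPeaks((1 - c) / (2 - c), 1 / (2 - c),
                                       "CN1"), c, tolerance = 1e-9)
    expect_equal(cellFractionFromPeaks((1 - c) / 2, (1 + c) / 2, "LOH"),
                 c, tolerance = 1e-9)
  }
})

test_that("purity is the rightmost supported density peak of the cell fractions", {
  p1 <- estimatePurity(rep(0.6, 25))
  expect_equal(alpha(p1), 0.6, tolerance = 1e-6)
  expect_length(densityPeaks(p1), 1)

  set.seed(31)
  pis <- c(rnorm(40, 0.3, 0.02), rnorm(40, 0.7, 0.02))
  pis <- pmin(pmax(pis, 0), 1)
  p2 <- estimatePurity(pis)
  expect_equal(alpha(p2), 0.7, tolerance = 0.03)
  expect_gte(length(densityPeaks(p2)), 2)

  p3 <- estimatePurity(sample(pis))
  expect_identical(alpha(p3), alpha(p2))

  expect_error(estimatePurity(numeric(0)), "no usable CNAs")
})

test_that("CNA clonality calls follow the relative-tolerance band", {
  expect_identical(classifyCnaClonality(0.58, 0.6, relTol = 0.1), "clonal")
  expect_identical(classifyCnaClonality(0.30, 0.6, relTol = 0.1),
                   "subclonal")
  expect_identical(classifyCnaClonality(0.6, 0.6, relTol = 0), "clonal")
  expect_identical(classifyCnaClonality(NA_real_, 0.6), "unassigned")
})

test_that("copy states follow read-ratio and allelic-imbalance evidence", {
  expect_identical(assignCopyState(1.0, 0.5, 0.5), "CN2")
  expect_identical(assignCopyState(1.0, 0.3, 0.7), "LOH")
  expect_identical(assignCopyState(0.75, 0.35, 0.65), "CN1")
  expect_identical(assignCopyState(0.1, 0.5, 0.5), "CN0")
  expect_identical(assignCopyState(1.4, 0.4, 0.6), "AMP")
  expect_error(assignCopyState(0, 0.5, 0.5), "positive")
})

test_that("clonal vs subclonal CNA labels are at least 90% correct on a synthetic cohort", {
  cfg <- simulationConfig(nSamples = 6L, nSegments = 25L,
                          segmentStateWeights = c(CN2 = 0.1, CN1 = 0.55,
                                                  CN0 = 0, LOH = 0.35,
                                                  AMP = 0),
                          subclonalCnaProb = 0.4, betaRange = c(0.2, 0.6),
                          probesPerSegment = 200L, bafNoiseSd = 0.03,
                          nSnvs = 0L, seed = 17L)
  correct <- 0L
  total <- 0L
  for (i in seq_len(cfg@nSamples)) {
    st <- simulateTumorSample(cfg, i)
    s <- analyzeCna(st$sample)
    lab <- S4Vectors::mcols(segments(s))$clonality
    truthClonal <- st$truth@segments$clonal
    usable <- which(!is.na(truthClonal) & lab != "unassigned" &
                      st$truth@segments$state %in% c("CN1", "LOH"))
    total <- total + length(usable)
    correct <- correct +
      sum((lab[usable] == "clonal") == truthClonal[usable])
  }
  expect_gt(total, 50)
  expect_gte(correct / total, 0.9)
})

test_that("analyzeCna fills segment metadata and a purity estimate", {
  cfg <- simulationConfig(nSamples = 1L, nSegments = 20L,
                          probesPerSegment = 100L, nSnvs = 0L, seed = 3L)
  st <- simulateTumorSample(cfg, 1L)
  s <- analyzeCna(st$sample)
  mc <- S4Vectors::mcols(segments(s))
  expect_true(all(c("mu1", "mu2", "cellFraction", "clonality") %in%
                    colnames(mc)))
  expect_s4_class(purity(s), "PurityEstimate")
  # CN2/AMP/CN0 segments never contribute cell fractions
  expect_true(all(is.na(mc$cellFraction[!mc$state %in% c("CN1", "LOH")])))
})
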