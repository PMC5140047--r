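test_that("substitution classification matches the pyrimidine-strand enumeration on all 96 cases and their reverse complements", {
  cases <- pyrimidineCases()
  expect_identical(nrow(cases), 96L)
  got <- classifyMutationType(cases$ref, cases$alt, cases$context)
  expect_identical(got, cases$label)
  # purine-strand representation of every case classifies identically
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gotRc <- classifyMutationType(unname(comp[cases$ref]),
                                unname(comp[cases$alt]),
                                revCompOracle(cases$context))
  expect_identical(gotRc, cases$label)
})

test_that("classification rejects malformed input", {
  expect_error(classifyMutationType("C", "C", "ACA"), "differ")
  expect_error(classifyMutationType("N", "A", "ANA"), "single bases")
  expect_error(classifyMutationType("C", "A", "AC"), "3-mer")
  expect_error(classifyMutationType("C", "A", "ATA"), "middle base")
})

test_that("the APOBEC TCW flag is correct for every case, both strands", {
  cases <- pyrimidineCases()
  expect_identical(isApobec(cases$ref, cases$alt, cases$context),
                   cases$apobec)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(isApobec(unname(comp[cases$ref]),
                            unname(comp[cases$alt]),
                            revCompOracle(cases$context)),
                   cases$apobec)
  expect_true(isApobec("C", "T", "TCA"))
  expect_false(isApobec("C", "A", "TCA"))
  expect_true(isApobec("G", "A", "TGA"))
})

test_that("per-sample summaries compute TNSM, rate, FT, FA and fractions", {
  muts <- data.frame(ref = c("C", "C", "T", "T"),
                     alt = c("A", "A", "C", "C"),
                     context = c("ACA", "ACT", "ATA", "CTG"),
                     stringsAsFactors = FALSE)
  s <- summarizeSample(muts, targetMb = 1)
  expect_identical(s@tnsm, 4L)
  expect_equal(s@ratePerMb, 4)
  expect_equal(s@ft, 0.5)
  expect_equal(unname(s@typeFractions["C>A_nonCpG"]), 0.5)
  expect_equal(unname(s@typeFractions["T>C"]), 0.5)

  # one mutation of each type -> each fraction 1/9
  nine <- data.frame(
    ref = c("C", "C", "C", "C", "C", "C", "T", "T", "T"),
    alt = c("A", "A", "G", "G", "T", "T", "A", "C", "G"),
    context = c("ACG", "ACA", "ACG", "ACA", "ACG", "ACA",
                "ATA", "ATA", "ATA"),
    stringsAsFactors = FALSE)
  s9 <- summarizeSample(nine, targetMb = 2)
  expect_equal(unname(s9@typeFractions), rep(1 / 9, 9))
  expect_equal(sum(s9@typeFractions), 1, tolerance = 1e-12)
  expect_equal(s9@ratePerMb, 4.5)

  s0 <- summarizeSample(muts[0, ], targetMb = 1)
  expect_identical(s0@tnsm, 0L)
  expect_true(all(is.na(s0@typeFractions)))
})

test_that("type fractions always sum to one and FT is one minus the transition fraction", {
  set.seed(8)
  cases <- pyrimidineCases()
  idx <- sample.int(96, 500, replace = TRUE)
  s <- summarizeSample(cases[idx, c("ref", "alt", "context")], targetMb = 30)
  expect_equal(sum(s@typeFractions), 1, tolerance = 1e-12)
  transitions <- c("C>T_CpG", "C>T_nonCpG", "T>C")
  expect_equal(s@ft + sum(s@typeFractions[transitions]), 1,
               tolerance = 1e-12)
})

test_that("a cohort generated at transversion fraction 0.62 is recovered within 0.02", {
  cfg <- simulationConfig(nSamples = 5L, nSegments = 10L,
                          probesPerSegment = 20L, nSnvs = 400L, seed = 13L)
  fts <- vapply(1:5, function(i) {
    st <- simulateTumorSample(cfg, i)
    summarizeSample(snvs(st$sample), targetMb = 36)@ft
  }, numeric(1))
  expect_lt(abs(mean(fts) - 0.62), 0.02)
})

test_that("APOBEC fraction does not depend on consequence when the generator couples none", {
  cfg <- simulationConfig(nSamples = 4L, nSegments = 10L,
                          probesPerSegment = 20L, nSnvs = 800L, seed = 29L)
  mc <- do.call(rbind, lapply(1:4, function(i) {
    st <- simulateTumorSample(cfg, i)
    as.data.frame(S4Vectors::mcols(snvs(st$sample)))
  }))
  ap <- isApobec(mc$ref, mc$alt, mc$context)
  faSyn <- mean(ap[mc$consequence == "synonymous"])
  faNon <- mean(ap[mc$consequence == "nonsynonymous"])
  expect_lt(abs(faSyn - faNon), 0.05)
})

test_that("covariate association reproduces the exact rank-sum p and handles Fisher tables", {
  expect_equal(covariateAssociation(c(1, 2, 3, 4, 5, 6),
                                    rep(c("a", "b"), each = 3)), 0.1)
  expect_equal(covariateAssociation(c(1, 2, 3, 1, 2, 3),
                                    rep(c("a", "b"), each = 3)), 1)
  expect_equal(covariateAssociation(matrix(c(10, 10, 20, 20), 2),
                                    test = "fisher"), 1)
  expect_error(covariateAssociation(1:5, rep("a", 5)), "two groups")
})

test_that("a one-standard-deviation group shift is detected in at least 80% of seeds", {
  set.seed(4)
  hits <- vapply(1:40, function(i) {
    x <- c(rnorm(50), rnorm(50, mean = 1))
    covariateAssociation(x, rep(c("a", "b"), each = 50)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the trait-by-feature screening grid enumerates one test per pair", {
  grid <- associationTestGrid(
    c("survival", "metastasis", "relapse", "copd", "grade"),
    c("tnsm", "ft", paste0("type", 1:9), "cna_fraction", "tp53", "kras"))
  expect_identical(nrow(grid), 70L)
  expect_identical(anyDuplicated(grid), 0L)
})
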