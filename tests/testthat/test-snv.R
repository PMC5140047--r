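test_that("clonal-null expected MAF matches the cell-enumeration oracle", {
  # boundary cases
  expect_equal(expectedMaf(1, 1, "CN1", "mutant_retained"), 1)
  expect_equal(expectedMaf(0.7, 0, "CN1", "mutant_retained"), 0.35)
  expect_equal(expectedMaf(0.7, 0, "CN2"), 0.35)
  # printed worked examples, against both the closed form and a literal
  # 10^6-cell enumeration
  expect_equal(expectedMaf(0.5, 0.5, "CN1", "mutant_retained"), 0.2857,
               tolerance = 1e-4)
  expect_equal(expectedMaf(0.5, 0.5, "CN1", "mutant_retained"),
               oracleMafEnumerated(0.5, 0.5, "CN1", "mutant_retained"),
               tolerance = 1e-9)
  expect_equal(expectedMaf(0.5, 0.5, "LOH", "mutant_duplicated"), 0.375)
  expect_equal(expectedMaf(0.5, 0.5, "LOH", "mutant_duplicated"),
               oracleMafEnumerated(0.5, 0.5, "LOH", "mutant_duplicated"),
               tolerance = 1e-9)
  # grid agreement with the class-counting oracle
  for (a in seq(0.1, 1, by = 0.15)) for (b in seq(0, 1, by = 0.2)) {
    expect_equal(expectedMaf(a, b, "CN1", "mutant_retained"),
                 oracleMaf(a, b, "CN1", "mutant_retained"), tolerance = 1e-12)
    expect_equal(expectedMaf(a, b, "CN1", "mutant_lost"),
                 oracleMaf(a, b, "CN1", "mutant_lost"), tolerance = 1e-12)
    expect_equal(expectedMaf(a, b, "LOH", "mutant_duplicated"),
                 oracleMaf(a, b, "LOH", "mutant_duplicated"),
                 tolerance = 1e-12)
    expect_equal(expectedMaf(a, b, "LOH", "wildtype_duplicated"),
                 oracleMaf(a, b, "LOH", "wildtype_duplicated"),
                 tolerance = 1e-12)
  }
  expect_error(expectedMaf(0.5, 0.5, "AMP", "none"), "excluded")
  expect_error(expectedMaf(0.5, 0.5, "CN0", "none"), "excluded")
})

test_that("the clonality test is the exact lower binomial tail", {
  expect_equal(clonalityTest(0, 30, 0.25), 0.75^30)
  expect_equal(clonalityTest(50, 50, 0.3), 1)
  expect_error(clonalityTest(5, 10, 0), "degenerate")
  expect_error(clonalityTest(5, 10, 1), "degenerate")
  expect_error(clonalityTest(11, 10, 0.5))
})

test_that("rejection probability is non-increasing in the cancer-cell fraction", {
  # a truly subclonal SNV with higher CCF looks more clonal: at fixed
  # depth the chance of falling below the rejection threshold shrinks
  alpha <- 0.6
  depth <- 100
  m0 <- alpha / 2
  kStar <- max(which(pbinom(0:depth, depth, m0) < 0.05)) - 1L
  rejection <- vapply(seq(0.05, 1, by = 0.05), function(ccf)
    pbinom(kStar, depth, alpha * ccf / 2), numeric(1))
  expect_true(all(diff(rejection) <= 1e-12))
})

test_that("clonality calls exclude AMP/CN0, threshold on p, and are conservative under unknown allele configuration", {
  tab <- data.frame(
    depth = c(100L, 100L, 100L, 100L, 100L),
    altCount = c(10L, 5L, 30L, 10L, 10L),
    segmentState = c("AMP", "CN0", "CN2", "CN1", "CN1"),
    beta = c(NA, NA, 0, 0.5, 0.5),
    alleleConfig = c(NA, NA, NA, "mutant_retained", NA),
    stringsAsFactors = FALSE)
  out <- callSnvClonality(tab, alpha = 0.6)
  expect_identical(out$clonality[1:2], c("excluded", "excluded"))
  expect_identical(out$clonality[3], "clonal")       # 30/100 at maf 0.3
  # row 4: known configuration; maf = 0.6/(2 - 0.3)
  expect_equal(out$expectedMaf[4], 0.6 / 1.7)
  # row 5: unknown configuration takes the larger of the two tail p-values
  p1 <- clonalityTest(10, 100, expectedMaf(0.6, 0.5, "CN1",
                                           "mutant_retained"))
  p2 <- clonalityTest(10, 100, expectedMaf(0.6, 0.5, "CN1", "mutant_lost"))
  expect_equal(out$pClonal[5], max(p1, p2))
  expect_gte(out$pClonal[5], out$pClonal[4])
  # missing beta is imputed to 0 and flagged
  tab2 <- data.frame(depth = 80L, altCount = 20L, segmentState = "CN1",
                     beta = NA_real_, stringsAsFactors = FALSE)
  out2 <- callSnvClonality(tab2, alpha = 0.6)
  expect_true(out2$betaImputed)
  expect_equal(out2$expectedMaf, 0.3)
})

test_that("fraction of subclonal mutations ignores excluded calls", {
  expect_equal(fsm(c("clonal", "subclonal", "subclonal", "clonal")), 0.5)
  expect_equal(fsm(rep("clonal", 5)), 0)
  expect_equal(fsm(c("subclonal", "excluded", "subclonal")), 1)
  expect_true(is.na(fsm(c("excluded", "excluded"))))
})

test_that("pooled FSM equals the mutation-count-weighted mean of per-sample FSM", {
  set.seed(12)
  samples <- lapply(1:8, function(i)
    sample(c("clonal", "subclonal", "excluded"), rpois(1, 40) + 5,
           replace = TRUE))
  pooled <- fsm(unlist(samples))
  perSample <- vapply(samples, fsm, numeric(1))
  weights <- vapply(samples, function(s)
    sum(s %in% c("clonal", "subclonal")), numeric(1))
  expect_equal(pooled, sum(perSample * weights) / sum(weights))
})

test_that("gene FSM tests agree with the hypergeometric enumeration oracle", {
  expect_equal(fsmGeneTest(c(5, 5), c(50, 50)), 1)
  expect_equal(fsmGeneTest(c(10, 0), c(50, 50)),
               oracleFisher2x2(10, 0, 50, 50), tolerance = 1e-10)
  expect_equal(fsmGeneTest(c(3, 9), c(40, 25)),
               fsmGeneTest(c(40, 25), c(3, 9)))
  e <- enrichment2x2(c(13, 87), c(8, 92))
  expect_equal(e$fractionA, 0.13)
  expect_equal(e$fractionB, 0.08)
  expect_equal(e$p, oracleFisher2x2(13, 87, 8, 92), tolerance = 1e-10)
  expect_equal(enrichment2x2(c(7, 13), c(7, 13))$p, 1)
})

test_that("a planted APOBEC enrichment of odds ratio 2 is detected in at least 90% of runs", {
  # 2,000 mutations split evenly; clonal APOBEC rate 0.08, subclonal odds
  # doubled
  pClonal <- 0.08
  oddsSub <- 2 * pClonal / (1 - pClonal)
  pSub <- oddsSub / (1 + oddsSub)
  set.seed(99)
  hits <- vapply(1:60, function(i) {
    kSub <- rbinom(1, 1000, pSub)
    kClo <- rbinom(1, 1000, pClonal)
    enrichment2x2(c(kSub, 1000 - kSub), c(kClo, 1000 - kClo))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("per-gene FSM summaries aggregate calls and test against the background", {
  gene <- c(rep("TP53", 10), rep("KRAS", 6), rep("OTHER", 80))
  calls <- c(rep("clonal", 9), "subclonal",          # TP53: fsm 0.1
             rep("clonal", 3), rep("subclonal", 3),  # KRAS: fsm 0.5
             rep(c("clonal", "subclonal"), 40))      # background: fsm 0.5
  out <- fsmByGene(gene, calls)
  expect_setequal(out$gene, c("TP53", "KRAS", "OTHER"))
  tp53 <- out[out$gene == "TP53", ]
  expect_equal(tp53$fsm, 0.1)
  expect_equal(tp53$p, fsmGeneTest(c(9, 1), c(43, 43)))
})

test_that("the sample-level SNV stage reproduces planted clonality beyond chance", {
  cfg <- simulationConfig(nSamples = 1L, purityRange = c(0.7, 0.7),
                          nSegments = 20L,
                          segmentStateWeights = c(CN2 = 0.6, CN1 = 0.2,
                                                  CN0 = 0, LOH = 0.2,
                                                  AMP = 0),
                          subclonalCnaProb = 0.3, nSnvs = 600L,
                          subclonalSnvProb = 0.5,
                          subclonalCcfRange = c(0.1, 0.4),
                          meanDepth = 150, seed = 21L)
  st <- simulateTumorSample(cfg, 1L)
  s <- analyzeCna(st$sample)
  s <- analyzeSnvClonality(s)
  mc <- S4Vectors::mcols(snvs(s))
  truth <- st$truth@snvs
  classified <- mc$clonality %in% c("clonal", "subclonal")
  called <- mc$clonality[classified] == "subclonal"
  planted <- !truth$clonal[classified]
  # low-CCF subclones at depth 150 are mostly detectable; clonal FP ~ 5%
  expect_gte(mean(called[planted]), 0.6)
  expect_lte(mean(called[!planted]), 0.1)
})
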