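#' @include AllClasses.R signatures.R
NULL

#' Build a synthetic tumor-genome simulation configuration
#'
#' Defaults describe a heavily CNA-disrupted lung adenocarcinoma cohort:
#' purity drawn uniformly on [0.2, 0.9]; 40 segments per sample dominated
#' by hemizygous deletions with LOH, amplification and copy-neutral
#' background in the proportions seen in such tumors; most deletions and
#' LOHs subclonal; 200 heterozygous SNP probes per segment with BAF noise
#' sd 0.03; 400 somatic SNVs per sample at mean depth 100, 55 percent of
#' them subclonal; a substitution-type spectrum dominated by C>A and C>T
#' with an overall transversion fraction of 0.62 and TCW contexts
#' upweighted so roughly 10 percent of mutations carry the APOBEC
#' signature. The methods vignette motivates each default.
#'
#' @param nSamples,purityRange,nSegments,segmentStateWeights,subclonalCnaProb
#'   see \linkS4class{SimulationConfig}
#' @param betaRange,probesPerSegment,bafNoiseSd,nSnvs,subclonalSnvProb see
#'   \linkS4class{SimulationConfig}
#' @param subclonalCcfRange,meanDepth,typeWeights,seed see
#'   \linkS4class{SimulationConfig}
#' @return a validated \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(nSamples = 50L,
                             purityRange = c(0.2, 0.9),
                             nSegments = 40L,
                             segmentStateWeights = c(CN2 = 0.10, CN1 = 0.50,
                                                     CN0 = 0.03, LOH = 0.13,
                                                     AMP = 0.24),
                             subclonalCnaProb = 0.6,
                             betaRange = c(0.2, 0.8),
                             probesPerSegment = 200L,
                             bafNoiseSd = 0.03,
                             nSnvs = 400L,
                             subclonalSnvProb = 0.55,
                             subclonalCcfRange = c(0.1, 0.8),
                             meanDepth = 100,
                             typeWeights = c("C>A_CpG" = 0.09,
                                             "C>A_nonCpG" = 0.33,
                                             "C>G_CpG" = 0.03,
                                             "C>G_nonCpG" = 0.08,
                                             "C>T_CpG" = 0.12,
                                             "C>T_nonCpG" = 0.16,
                                             "T>A" = 0.05,
                                             "T>C" = 0.10,
                                             "T>G" = 0.04),
                             seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples),
      purityRange = as.numeric(purityRange),
      nSegments = as.integer(nSegments),
      segmentStateWeights = segmentStateWeights[CNA_STATES],
      subclonalCnaProb = subclonalCnaProb,
      betaRange = as.numeric(betaRange),
      probesPerSegment = as.integer(probesPerSegment),
      bafNoiseSd = bafNoiseSd,
      nSnvs = as.integer(nSnvs),
      subclonalSnvProb = subclonalSnvProb,
      subclonalCcfRange = as.numeric(subclonalCcfRange),
      meanDepth = meanDepth,
      typeWeights = typeWeights[MUTATION_TYPES],
      seed = as.integer(seed))
}

# Analytic BAF peak pair implied by (state, c) with c the fraction of ALL
# cells carrying the CNA; this is the closed form the downstream mixture
# fit inverts.
bafPeaksForState <- function(state, c) {
  switch(state,
    CN2 = c(0.5, 0.5),
    CN0 = c(0.5, 0.5),                       # residual signal is germline het
    CN1 = c((1 - c) / (2 - c), 1 / (2 - c)),
    LOH = c((1 - c) / 2, (1 + c) / 2),
    AMP = c(1 / (2 + c), (1 + c) / (2 + c)))
}

# Expected tumor/normal read-depth ratio for a segment.
readRatioForState <- function(state, c) {
  switch(state,
    CN2 = 1,
    CN1 = (2 - c) / 2,
    CN0 = 1 - c,
    LOH = 1,
    AMP = (2 + c) / 2)
}

# Analytic clonal-null / subclonal expected MAF used by the generator. For
# clonal mutations this matches expectedMaf() on the supported states and
# extends it to CN0/AMP (which the tester excludes); subclonal mutations
# carry one mutant copy in a fraction ccf of tumor cells.
generatorMaf <- function(alpha, beta, state, alleleConfig, clonal, ccf) {
  total <- switch(state,
    CN2 = 2, LOH = 2,
    CN1 = 2 - alpha * beta,
    CN0 = 2 - 2 * alpha * beta,
    AMP = 2 + alpha * beta)
  if (clonal) {
    mutant <- switch(state,
      CN2 = alpha,
      CN1 = if (alleleConfig == "mutant_retained") alpha else
        alpha * (1 - beta),
      LOH = if (alleleConfig == "mutant_duplicated") alpha * (1 + beta) else
        alpha * (1 - beta),
      CN0 = alpha * (1 - beta),
      AMP = if (alleleConfig == "mutant_duplicated") alpha * (1 + beta) else
        alpha)
    mutant / total
  } else {
    alpha * ccf / total
  }
}

# Draw a trinucleotide context consistent with a collapsed type label. TCW
# contexts are upweighted for C>T/C>G outside CpG so the cohort APOBEC
# fraction lands near 10 percent.
drawContext <- function(type, apobecBoost = 0.325) {
  ref <- substr(type, 1, 1)
  first <- sample(c("A", "C", "G", "T"), 1)
  if (ref == "T") return(paste0(first, "T", sample(c("A", "C", "G", "T"), 1)))
  if (grepl("_CpG$", type)) return(paste0(first, "C", "G"))
  # nonCpG C: third base is A, C or T
  if (type %in% c("C>G_nonCpG", "C>T_nonCpG") &&
      stats::runif(1) < apobecBoost) {
    # boosted TCW draw; non-boosted draws still land in TCW 1/6 of the
    # time, so the cohort APOBEC fraction is 0.24 * (b + (1-b)/6) ~ 0.105

    return(paste0("T", "C", sample(c("A", "T"), 1)))
  }
  paste0(first, "C", sample(c("A", "C", "T"), 1))
}

#' Simulate one tumor sample with ground truth
#'
#' Realizes the tumor/normal admixture model the analysis stages assume.
#' A purity alpha is drawn, CNA segments are laid out with copy states and
#' (possibly subclonal) tumor-cell fractions beta, and heterozygous-probe
#' BAFs are drawn around the analytic peak positions implied by
#' (alpha, beta, state) with truncated-Gaussian noise on [0, 1]. Somatic
#' SNVs are placed on the segments, labeled clonal or subclonal (with a
#' cancer-cell fraction), assigned an allele configuration uniformly at
#' random where the state allows both, and their mutant read counts drawn
#' binomially at the analytic expected mutant-allele fraction with
#' Poisson-distributed depth. Trinucleotide contexts realize the
#' configured substitution-type spectrum; half the mutations are reported
#' on the purine strand. Deterministic given the config seed and the
#' sample index.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param sampleIndex 1-based index of the sample within the cohort
#' @return a list with elements \code{sample} (a
#'   \linkS4class{TumorSample}) and \code{truth} (a
#'   \linkS4class{GroundTruth})
#' @export
simulateTumorSample <- function(config, sampleIndex = 1L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(deriveSeed(config@seed, sampleIndex))
  sid <- sprintf("S%03d", sampleIndex)
  alpha <- stats::runif(1, config@purityRange[1], config@purityRange[2])

  nSeg <- config@nSegments
  w <- config@segmentStateWeights
  state <- sample(names(w), nSeg, replace = TRUE, prob = w / sum(w))
  isSub <- state != "CN2" & stats::runif(nSeg) < config@subclonalCnaProb
  beta <- ifelse(state == "CN2", NA_real_,
                 ifelse(isSub,
                        stats::runif(nSeg, config@betaRange[1],
                                     config@betaRange[2]), 1))
  cFrac <- ifelse(is.na(beta), NA_real_, alpha * beta)
  readRatio <- vapply(seq_len(nSeg), function(i)
    readRatioForState(state[i], if (is.na(cFrac[i])) 0 else cFrac[i]),
    numeric(1)) * exp(stats::rnorm(nSeg, 0, 0.02))

  # segment layout: probe spacing 5 kb, one 10 Mb slot per segment,
  # cycling over 22 autosomes
  spacing <- 5000L
  segWidth <- config@probesPerSegment * spacing
  chrom <- paste0("chr", (seq_len(nSeg) - 1L) %% 22L + 1L)
  slot <- (seq_len(nSeg) - 1L) %/% 22L
  segStart <- slot * 10000000L + 1L
  segEnd <- segStart + segWidth - 1L
  segments <- GRanges(chrom, IRanges(segStart, segEnd))
  S4Vectors::mcols(segments) <- DataFrame(
    segmentId = seq_len(nSeg), state = state, readRatio = readRatio)

  # probes
  nP <- config@probesPerSegment
  probeList <- lapply(seq_len(nSeg), function(i) {
    pk <- bafPeaksForState(state[i], if (is.na(cFrac[i])) 0 else cFrac[i])
    side <- sample(c(1L, 2L), nP, replace = TRUE)
    baf <- rtruncnorm01(nP, pk[side], config@bafNoiseSd)
    pos <- segStart[i] + (seq_len(nP) - 1L) * spacing
    list(chrom = rep(chrom[i], nP), pos = pos, baf = baf,
         segmentId = rep(i, nP))
  })
  probes <- GRanges(
    unlist(lapply(probeList, `[[`, "chrom")),
    IRanges(unlist(lapply(probeList, `[[`, "pos")), width = 1L))
  S4Vectors::mcols(probes) <- DataFrame(
    baf = unlist(lapply(probeList, `[[`, "baf")),
    lrr = log2(readRatio[unlist(lapply(probeList, `[[`, "segmentId"))]),
    segmentId = unlist(lapply(probeList, `[[`, "segmentId")))

  # SNVs: never placed in CN0 segments (no template left to sequence)
  nSnv <- config@nSnvs
  snvGr <- GRanges()
  snvTruth <- data.frame(snvId = integer(), segmentId = integer(),
                         state = character(), clonal = logical(),
                         ccf = numeric(), alleleConfig = character(),
                         expectedMaf = numeric())
  if (nSnv > 0L) {
    eligible <- which(state != "CN0")
    segIdx <- sample(eligible, nSnv, replace = TRUE)
    snvState <- state[segIdx]
    snvBeta <- ifelse(is.na(beta[segIdx]), 0, beta[segIdx])
    clonal <- stats::runif(nSnv) >= config@subclonalSnvProb
    ccf <- ifelse(clonal, 1,
                  stats::runif(nSnv, config@subclonalCcfRange[1],
                               config@subclonalCcfRange[2]))
    alleleConfig <- rep("none", nSnv)
    for (i in seq_len(nSnv)) {
      if (!clonal[i] || snvBeta[i] == 0) next
      alleleConfig[i] <- switch(snvState[i],
        CN1 = sample(c("mutant_retained", "mutant_lost"), 1),
        LOH = ,
        AMP = sample(c("mutant_duplicated", "wildtype_duplicated"), 1),
        "none")
    }
    maf <- vapply(seq_len(nSnv), function(i)
      generatorMaf(alpha, snvBeta[i], snvState[i], alleleConfig[i],
                   clonal[i], ccf[i]), numeric(1))
    maf <- pmin(pmax(maf, 0), 1)
    # a mutation on the lost allele of a fully clonal deletion leaves no
    # mutant template: it can never be observed, so it never enters a
    # somatic call set
    visible <- maf > 0
    segIdx <- segIdx[visible]
    snvState <- snvState[visible]
    snvBeta <- snvBeta[visible]
    clonal <- clonal[visible]
    ccf <- ccf[visible]
    alleleConfig <- alleleConfig[visible]
    maf <- maf[visible]
    nSnv <- sum(visible)
    depth <- pmax(stats::rpois(nSnv, config@meanDepth), 1L)
    altCount <- stats::rbinom(nSnv, depth, maf)

    type <- sample(MUTATION_TYPES, nSnv, replace = TRUE,
                   prob = config@typeWeights / sum(config@typeWeights))
    ref <- substr(type, 1, 1)
    alt <- substr(type, 3, 3)
    context <- vapply(type, drawContext, character(1))
    flip <- stats::runif(nSnv) < 0.5
    ref[flip] <- unname(COMPLEMENT[ref[flip]])
    alt[flip] <- unname(COMPLEMENT[alt[flip]])
    context[flip] <- revComp(context[flip])

    pos <- segStart[segIdx] + as.integer(
      floor(stats::runif(nSnv, 0, segWidth - 1))) + 1L
    snvGr <- GRanges(chrom[segIdx], IRanges(pmin(pos, segEnd[segIdx]),
                                            width = 1L))
    S4Vectors::mcols(snvGr) <- DataFrame(
      snvId = seq_len(nSnv),
      ref = ref, alt = alt,
      depth = as.integer(depth), altCount = as.integer(altCount),
      gene = sprintf("G%03d", sample.int(150L, nSnv, replace = TRUE)),
      consequence = sample(c("synonymous", "nonsynonymous", "other"),
                           nSnv, replace = TRUE,
                           prob = c(0.25, 0.70, 0.05)),
      context = context,
      segmentId = segIdx)
    snvTruth <- data.frame(snvId = seq_len(nSnv), segmentId = segIdx,
                           state = snvState, clonal = clonal, ccf = ccf,
                           alleleConfig = alleleConfig, expectedMaf = maf,
                           stringsAsFactors = FALSE)
  }

  sampleObj <- new("TumorSample", sampleId = sid, segments = segments,
                   probes = probes, snvs = snvGr, purity = NULL)
  truth <- new("GroundTruth", sampleId = sid, purity = alpha,
               segments = data.frame(segmentId = seq_len(nSeg),
                                     state = state, beta = beta,
                                     cellFraction = cFrac,
                                     clonal = ifelse(is.na(beta), NA, !isSub),
                                     stringsAsFactors = FALSE),
               snvs = snvTruth)
  list(sample = sampleObj, truth = truth)
}

#' Simulate a cohort of tumor samples
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a list with elements \code{samples} (list of
#'   \linkS4class{TumorSample}) and \code{truths} (list of
#'   \linkS4class{GroundTruth})
#' @export
simulateCohort <- function(config) {
  out <- lapply(seq_len(config@nSamples),
                function(i) simulateTumorSample(config, i))
  list(samples = lapply(out, `[[`, "sample"),
       truths = lapply(out, `[[`, "truth"))
}

#' Simulate a methylation cohort with planted trait associations
#'
#' Generates a CpG-probe beta-value matrix, a mutation-signature-like
#' trait driven by clinical covariates (smoking status, age, stage, sex),
#' and probe annotations (CGI/nonCGI/open-sea; promoter/body/3'UTR/
#' intergenic). Exactly \code{nAssoc} probes carry a planted positive
#' association with the covariate-independent component of the trait:
#' their methylation is shifted by \code{effectSize} (in probe-noise
#' standard deviations per trait residual standard deviation), giving a
#' partial correlation of \code{effectSize / sqrt(1 + effectSize^2)}.
#'
#' @param nSamples number of samples (columns)
#' @param nProbes number of CpG probes (rows)
#' @param nAssoc number of probes with a planted association
#'   (\code{<= nProbes})
#' @param effectSize standardized planted effect; 0 plants nothing
#' @param seed random seed
#' @return a list with \code{methylation} (probes x samples matrix),
#'   \code{trait}, \code{covariates} (data.frame), \code{annotation}
#'   (probe, cgi, region), and \code{truth} (data.frame of planted probes;
#'   zero rows when \code{effectSize} is 0)
#' @export
simulateMethylationDataset <- function(nSamples = 500L, nProbes = 5000L,
                                       nAssoc = 50L, effectSize = 0.5,
                                       seed = 1L) {
  if (nAssoc > nProbes)
    stop("nAssoc must not exceed nProbes")
  stopifnot(nSamples >= 10, nProbes >= 1, nAssoc >= 0)
  set.seed(as.integer(seed))
  smoking <- factor(sample(c("never", "former", "current"), nSamples,
                           replace = TRUE, prob = c(0.07, 0.42, 0.51)),
                    levels = c("never", "former", "current"))
  age <- round(stats::runif(nSamples, 44, 79))
  stage <- factor(sample(c("I", "II", "III"), nSamples, replace = TRUE,
                         prob = c(0.50, 0.30, 0.20)),
                  levels = c("I", "II", "III"))
  sex <- factor(sample(c("male", "female"), nSamples, replace = TRUE,
                       prob = c(0.82, 0.18)), levels = c("male", "female"))
  covariates <- data.frame(smoking = smoking, age = age, stage = stage,
                           sex = sex)
  resid <- stats::rnorm(nSamples)
  trait <- 2 * (smoking != "never") + 0.02 * (age - 65) +
    0.3 * (stage == "II") + 0.5 * (stage == "III") +
    0.2 * (sex == "male") + resid
  z <- as.numeric(scale(resid))

  probeIds <- sprintf("cg%08d", seq_len(nProbes))
  cgi <- sample(c("CGI", "nonCGI", "open-sea"), nProbes, replace = TRUE,
                prob = c(0.31, 0.36, 0.33))
  region <- sample(c("promoter", "body", "3'UTR", "intergenic"), nProbes,
                   replace = TRUE, prob = c(0.30, 0.40, 0.10, 0.20))
  baseline <- numeric(nProbes)
  baseline[cgi == "CGI"] <- stats::rbeta(sum(cgi == "CGI"), 2, 8)
  baseline[cgi == "nonCGI"] <- stats::rbeta(sum(cgi == "nonCGI"), 2, 4)
  baseline[cgi == "open-sea"] <- stats::rbeta(sum(cgi == "open-sea"), 5, 2)

  noiseSd <- 0.05
  meth <- matrix(stats::rnorm(nProbes * nSamples, 0, noiseSd),
                 nrow = nProbes)
  planted <- if (effectSize > 0 && nAssoc > 0)
    sort(sample.int(nProbes, nAssoc)) else integer(0)
  if (length(planted))
    meth[planted, ] <- meth[planted, ] +
      matrix(rep(effectSize * noiseSd * z, each = length(planted)),
             nrow = length(planted))
  meth <- pmin(pmax(meth + baseline, 0.001), 0.999)
  rownames(meth) <- probeIds
  colnames(meth) <- sprintf("S%03d", seq_len(nSamples))

  list(methylation = meth,
       trait = trait,
       covariates = covariates,
       annotation = data.frame(probe = probeIds, cgi = cgi, region = region,
                               stringsAsFactors = FALSE),
       truth = data.frame(probe = probeIds[planted],
                          effectSize = rep(effectSize, length(planted)),
                          stringsAsFactors = FALSE))
}
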