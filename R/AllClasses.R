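#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

CNA_STATES <- c("CN2", "CN1", "CN0", "LOH", "AMP")
ALLELE_CONFIGS <- c("mutant_retained", "mutant_lost", "mutant_duplicated",
                    "wildtype_duplicated", "none")
CLONALITY_LEVELS <- c("clonal", "subclonal", "unassigned")
SNV_CLONALITY_LEVELS <- c("clonal", "subclonal", "excluded")

#' Configuration for the synthetic tumor-genome generator
#'
#' Holds every tunable of the simulator: cohort size, tumor purity range,
#' per-sample CNA segment layout (copy-state mixture, probe counts, BAF
#' noise), somatic SNV counts with clonal/subclonal composition, sequencing
#' depth, substitution-type spectrum, and the random seed. Defaults describe
#' a heavily CNA-disrupted, smoking-dominated adenocarcinoma cohort; see the
#' methods vignette for the rationale behind each value.
#'
#' @slot nSamples number of tumor samples to simulate
#' @slot purityRange interval in (0,1] from which tumor purity is drawn
#' @slot nSegments CNA/copy-neutral segments per sample
#' @slot segmentStateWeights named non-negative weights over
#'   \code{c("CN2","CN1","CN0","LOH","AMP")}
#' @slot subclonalCnaProb probability a CNA is subclonal (beta < 1)
#' @slot betaRange interval in (0,1] for subclonal CNA tumor-cell fractions
#' @slot probesPerSegment heterozygous SNP probes simulated per segment
#' @slot bafNoiseSd standard deviation of truncated-Gaussian BAF noise
#' @slot nSnvs somatic point mutations per sample
#' @slot subclonalSnvProb probability an SNV is subclonal
#' @slot subclonalCcfRange interval in (0,1) for subclonal cancer-cell fractions
#' @slot meanDepth mean sequencing depth (Poisson) at SNV loci
#' @slot typeWeights named weights over the nine substitution-type labels
#' @slot seed integer random seed
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSamples = "integer",
    purityRange = "numeric",
    nSegments = "integer",
    segmentStateWeights = "numeric",
    subclonalCnaProb = "numeric",
    betaRange = "numeric",
    probesPerSegment = "integer",
    bafNoiseSd = "numeric",
    nSnvs = "integer",
    subclonalSnvProb = "numeric",
    subclonalCcfRange = "numeric",
    meanDepth = "numeric",
    typeWeights = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  bad <- function(field, msg) sprintf("invalid '%s': %s", field, msg)
  msgs <- character()
  chkRange <- function(x, field, lo, hi, loOpen = FALSE, hiOpen = FALSE) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] ||
        x[1] < lo || x[2] > hi ||
        (loOpen && x[1] <= lo) || (hiOpen && x[2] >= hi))
      bad(field, sprintf("must be an ordered interval within %s%s, %s%s",
                         if (loOpen) "(" else "[", lo, hi,
                         if (hiOpen) ")" else "]"))
    else character()
  }
  chkProb <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      bad(field, "must be a probability in [0, 1]") else character()
  }
  msgs <- c(msgs,
    if (object@nSamples < 1L) bad("nSamples", "must be >= 1"),
    chkRange(object@purityRange, "purityRange", 0, 1, loOpen = TRUE),
    if (object@nSegments < 1L) bad("nSegments", "must be >= 1"),
    chkProb(object@subclonalCnaProb, "subclonalCnaProb"),
    chkRange(object@betaRange, "betaRange", 0, 1, loOpen = TRUE),
    if (object@probesPerSegment < 1L) bad("probesPerSegment", "must be >= 1"),
    if (object@bafNoiseSd < 0) bad("bafNoiseSd", "must be >= 0"),
    if (object@nSnvs < 0L) bad("nSnvs", "must be >= 0"),
    chkProb(object@subclonalSnvProb, "subclonalSnvProb"),
    chkRange(object@subclonalCcfRange, "subclonalCcfRange", 0, 1,
             loOpen = TRUE, hiOpen = TRUE),
    if (!is.finite(object@meanDepth) || object@meanDepth <= 0)
      bad("meanDepth", "must be > 0"))
  w <- object@segmentStateWeights
  if (!setequal(names(w), CNA_STATES) || any(w < 0) || sum(w) <= 0)
    msgs <- c(msgs, bad("segmentStateWeights",
      "must be non-negative weights named CN2, CN1, CN0, LOH, AMP"))
  tw <- object@typeWeights
  if (!setequal(names(tw), MUTATION_TYPES) || any(tw < 0) || sum(tw) <= 0)
    msgs <- c(msgs, bad("typeWeights",
      "must be non-negative weights named after the nine substitution types"))
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated tumor sample
#'
#' @slot sampleId sample identifier
#' @slot purity true tumor purity alpha
#' @slot segments data.frame of per-segment truth (state, beta, cell
#'   fraction, clonal flag)
#' @slot snvs data.frame of per-SNV truth (clonal flag, cancer-cell
#'   fraction, allele configuration, expected mutant-allele fraction)
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    sampleId = "character",
    purity = "numeric",
    segments = "data.frame",
    snvs = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character()
  if (length(object@purity) != 1 || object@purity <= 0 || object@purity > 1)
    msgs <- c(msgs, "purity must be a single value in (0, 1]")
  if (nrow(object@snvs) && any(object@snvs$clonal & object@snvs$ccf != 1))
    msgs <- c(msgs, "clonal SNVs must have cancer-cell fraction exactly 1")
  if (length(msgs)) msgs else TRUE
})

#' Tumor purity estimate from CNA cell fractions
#'
#' Purity is taken as the location of the rightmost sufficiently supported
#' peak of the kernel density of per-CNA cell fractions (pi); each density
#' peak is interpreted as one clone, the rightmost as the primary clone.
#'
#' @slot alpha estimated tumor purity in (0,1]
#' @slot piValues per-CNA cell fractions the estimate is based on
#' @slot densityPeaks retained density peak locations, ascending
#' @slot bandwidth kernel density bandwidth used
#' @exportClass PurityEstimate
setClass("PurityEstimate",
  representation(
    alpha = "numeric",
    piValues = "numeric",
    densityPeaks = "numeric",
    bandwidth = "numeric"
  )
)

setValidity("PurityEstimate", function(object) {
  msgs <- character()
  if (length(object@alpha) != 1 || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a single value in (0, 1]")
  if (length(object@densityPeaks) &&
      is.unsorted(object@densityPeaks, strictly = FALSE))
    msgs <- c(msgs, "densityPeaks must be in ascending order")
  if (length(object@densityPeaks) &&
      abs(max(object@densityPeaks) - object@alpha) > 1e-8)
    msgs <- c(msgs, "alpha must equal the rightmost density peak")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("PurityEstimateOrNULL", c("PurityEstimate", "NULL"))

#' Per-sample container for clonality analysis
#'
#' Ties together everything the pipeline knows about one tumor specimen:
#' CNA segments (a \code{GRanges} with copy state, fitted BAF peaks, cell
#' fraction and clonality call in its metadata columns), heterozygous
#' SNP-array probes (a \code{GRanges} with BAF/LRR), somatic SNVs (a
#' \code{GRanges} with read counts, trinucleotide context, expected
#' mutant-allele fraction, clonality p-value and call), and the purity
#' estimate once computed.
#'
#' @slot sampleId sample identifier
#' @slot segments CNA segments as a \code{GRanges}
#' @slot probes heterozygous SNP probes as a \code{GRanges}
#' @slot snvs somatic point mutations as a \code{GRanges}
#' @slot purity a \linkS4class{PurityEstimate} or \code{NULL}
#' @exportClass TumorSample
setClass("TumorSample",
  representation(
    sampleId = "character",
    segments = "GRanges",
    probes = "GRanges",
    snvs = "GRanges",
    purity = "PurityEstimateOrNULL"
  )
)

setValidity("TumorSample", function(object) {
  msgs <- character()
  seg <- object@segments
  if (length(seg)) {
    need <- c("state")
    miss <- setdiff(need, colnames(mcols(seg)))
    if (length(miss))
      msgs <- c(msgs, paste("segments lack metadata column(s):",
                            paste(miss, collapse = ", ")))
    else if (!all(mcols(seg)$state %in% CNA_STATES))
      msgs <- c(msgs, "segment states must be CN2, CN1, CN0, LOH or AMP")
  }
  snv <- object@snvs
  if (length(snv)) {
    need <- c("ref", "alt", "depth", "altCount")
    miss <- setdiff(need, colnames(mcols(snv)))
    if (length(miss))
      msgs <- c(msgs, paste("snvs lack metadata column(s):",
                            paste(miss, collapse = ", ")))
    else if (any(mcols(snv)$altCount > mcols(snv)$depth |
                 mcols(snv)$altCount < 0))
      msgs <- c(msgs, "snvs must satisfy 0 <= altCount <= depth")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-sample mutation-signature summary
#'
#' @slot sampleId sample identifier
#' @slot tnsm total number of somatic point mutations
#' @slot typeFractions named fractions over the nine substitution types
#'   (sum to 1 when \code{tnsm > 0}; all \code{NA} otherwise)
#' @slot ft fraction of transversions
#' @slot fa fraction of APOBEC TCW-motif mutations
#' @slot ratePerMb mutations per megabase of sequencing target
#' @exportClass SignatureSummary
setClass("SignatureSummary",
  representation(
    sampleId = "character",
    tnsm = "integer",
    typeFractions = "numeric",
    ft = "numeric",
    fa = "numeric",
    ratePerMb = "numeric"
  )
)

setValidity("SignatureSummary", function(object) {
  msgs <- character()
  f <- object@typeFractions
  if (!identical(names(f), MUTATION_TYPES))
    msgs <- c(msgs, "typeFractions must be named by the nine substitution types")
  if (object@tnsm > 0L) {
    if (abs(sum(f) - 1) > 1e-9)
      msgs <- c(msgs, "nine type fractions must sum to 1")
    if (!is.na(object@fa) && (object@fa < 0 || object@fa > 1))
      msgs <- c(msgs, "fa must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
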