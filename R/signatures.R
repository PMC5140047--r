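#' @include AllClasses.R
NULL

#' The nine point-mutation type labels
#'
#' Substitutions are collapsed to the pyrimidine-reference strand; C-reference
#' classes are split by CpG dinucleotide context (reference C followed by G),
#' T-reference classes are not, giving nine types in total.
#'
#' @format character vector of length 9
#' @export
MUTATION_TYPES <- c("C>A_CpG", "C>A_nonCpG", "C>G_CpG", "C>G_nonCpG",
                    "C>T_CpG", "C>T_nonCpG", "T>A", "T>C", "T>G")

TRANSVERSION_TYPES <- c("C>A_CpG", "C>A_nonCpG", "C>G_CpG", "C>G_nonCpG",
                        "T>A", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revComp <- function(s) {
  # reverse-complement of ACGT strings (vectorized)
  vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(COMPLEMENT[ch])), collapse = ""), character(1))
}

checkBases <- function(ref, alt, context) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("ref and alt must be single bases A, C, G or T")
  if (any(ref == alt))
    stop("ref and alt must differ")
  cs <- strsplit(context, "")
  if (any(nchar(context) != 3L) ||
      !all(unlist(cs) %in% bases))
    stop("context must be an ACGT 3-mer centered on the mutated base")
  mid <- substr(context, 2, 2)
  if (any(mid != ref))
    stop("context middle base must equal ref")
  invisible(TRUE)
}

# Collapse to the pyrimidine strand: purine references are reverse
# complemented together with alt and context.
strandCollapse <- function(ref, alt, context) {
  flip <- ref %in% c("A", "G")
  ref[flip] <- unname(COMPLEMENT[ref[flip]])
  alt[flip] <- unname(COMPLEMENT[alt[flip]])
  context[flip] <- revComp(context[flip])
  list(ref = ref, alt = alt, context = context)
}

#' Classify a point mutation into one of the nine substitution types
#'
#' Purine-reference mutations are reverse complemented (ref, alt and
#' trinucleotide context together) to the pyrimidine representation.
#' C-reference substitutions are subdivided by whether the reference C is
#' followed by a G after strand collapse (CpG dinucleotide context);
#' T-reference substitutions are not subdivided.
#'
#' @param ref,alt reference and alternate bases (single characters)
#' @param context reference-strand trinucleotide centered on the mutated base
#' @return character vector of labels from \code{\link{MUTATION_TYPES}}
#' @examples
#' classifyMutationType("C", "A", "ACG")  # "C>A_CpG"
#' classifyMutationType("G", "T", "CGT")  # same mutation, other strand
#' @export
classifyMutationType <- function(ref, alt, context) {
  checkBases(ref, alt, context)
  s <- strandCollapse(ref, alt, context)
  base <- paste0(s$ref, ">", s$alt)
  cpg <- substr(s$context, 3, 3) == "G"
  ifelse(s$ref == "C",
         paste0(base, ifelse(cpg, "_CpG", "_nonCpG")),
         base)
}

#' Flag APOBEC-signature (TCW-motif) mutations
#'
#' A mutation is APOBEC-mediated if, after collapse to the pyrimidine
#' strand, it is a C-to-T or C-to-G substitution inside a TCW motif
#' (context TCA or TCT, W = A or T).
#'
#' @inheritParams classifyMutationType
#' @return logical vector
#' @examples
#' isApobec("C", "T", "TCA")  # TRUE
#' isApobec("C", "A", "TCA")  # FALSE: C>A is not part of the signature
#' isApobec("G", "A", "TGA")  # TRUE: reverse complement of TCA with C>T
#' @export
isApobec <- function(ref, alt, context) {
  checkBases(ref, alt, context)
  s <- strandCollapse(ref, alt, context)
  s$context %in% c("TCA", "TCT") & s$alt %in% c("T", "G")
}

#' Whether a substitution type label is a transversion
#'
#' Transversions exchange a purine for a pyrimidine: on the collapsed strand
#' these are C>A, C>G, T>A and T>G (CpG split immaterial).
#'
#' @param type labels from \code{\link{MUTATION_TYPES}}
#' @return logical vector
#' @export
isTransversion <- function(type) {
  stopifnot(all(type %in% MUTATION_TYPES))
  type %in% TRANSVERSION_TYPES
}

#' Summarize the mutation signature of one sample
#'
#' Computes the total number of somatic point mutations (TNSM), the nine
#' substitution-type fractions, the fraction of transversions (FT), the
#' fraction of APOBEC TCW-motif mutations (FA), and the mutation rate per
#' megabase of sequencing target.
#'
#' @param mutations a \code{data.frame} (or \code{GRanges} metadata) with
#'   columns \code{ref}, \code{alt} and \code{context}
#' @param targetMb size of the sequenced target region in megabases
#' @param sampleId sample label carried into the summary
#' @return a \linkS4class{SignatureSummary}; with zero mutations the
#'   fractions are \code{NA}
#' @export
summarizeSample <- function(mutations, targetMb, sampleId = "sample") {
  stopifnot(is.numeric(targetMb), length(targetMb) == 1, targetMb > 0)
  if (inherits(mutations, "GRanges"))
    mutations <- as.data.frame(S4Vectors::mcols(mutations))
  n <- nrow(mutations)
  if (n == 0L) {
    return(new("SignatureSummary", sampleId = sampleId, tnsm = 0L,
               typeFractions = stats::setNames(rep(NA_real_, 9), MUTATION_TYPES),
               ft = NA_real_, fa = NA_real_, ratePerMb = 0))
  }
  type <- classifyMutationType(mutations$ref, mutations$alt, mutations$context)
  counts <- table(factor(type, levels = MUTATION_TYPES))
  fr <- as.numeric(counts) / n
  names(fr) <- MUTATION_TYPES
  new("SignatureSummary",
      sampleId = sampleId,
      tnsm = n,
      typeFractions = fr,
      ft = mean(isTransversion(type)),
      fa = mean(isApobec(mutations$ref, mutations$alt, mutations$context)),
      ratePerMb = n / targetMb)
}

#' Tabulate signature summaries across a cohort
#'
#' @param summaries a list of \linkS4class{SignatureSummary} objects
#' @return a \code{data.frame} with one row per sample: \code{sampleId},
#'   \code{tnsm}, \code{ratePerMb}, \code{ft}, \code{fa} and the nine type
#'   fractions
#' @export
signatureTable <- function(summaries) {
  stopifnot(all(vapply(summaries, is, TRUE, "SignatureSummary")))
  base <- data.frame(
    sampleId = vapply(summaries, function(s) s@sampleId, character(1)),
    tnsm = vapply(summaries, function(s) s@tnsm, integer(1)),
    ratePerMb = vapply(summaries, function(s) s@ratePerMb, numeric(1)),
    ft = vapply(summaries, function(s) s@ft, numeric(1)),
    fa = vapply(summaries, function(s) s@fa, numeric(1)),
    stringsAsFactors = FALSE)
  fr <- t(vapply(summaries, function(s) s@typeFractions, numeric(9)))
  colnames(fr) <- MUTATION_TYPES
  cbind(base, as.data.frame(fr, check.names = FALSE))
}

#' Association between a signature statistic and a covariate
#'
#' Nonparametric association testing between per-sample mutation-signature
#' statistics and sample covariates: the two-sided Wilcoxon rank-sum test
#' for a numeric statistic against a two-level grouping, or Fisher's exact
#' test for a 2x2 contingency table. Exact Wilcoxon p-values are used when
#' there are no ties and fewer than 50 observations per group (the
#' \code{stats::wilcox.test} default); the normal approximation otherwise.
#'
#' @param values numeric statistic per sample (Wilcoxon), or a 2x2 count
#'   matrix (Fisher)
#' @param group two-level factor of the same length as \code{values}
#'   (ignored for Fisher)
#' @param test \code{"wilcoxon"} or \code{"fisher"}
#' @return the two-sided p-value
#' @examples
#' covariateAssociation(c(1, 2, 3, 4, 5, 6),
#'                      rep(c("a", "b"), each = 3))  # 0.1
#' @export
covariateAssociation <- function(values, group = NULL,
                                 test = c("wilcoxon", "fisher")) {
  test <- match.arg(test)
  if (test == "fisher") {
    m <- as.matrix(values)
    stopifnot(identical(dim(m), c(2L, 2L)))
    return(stats::fisher.test(m)$p.value)
  }
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("covariate association needs at least two groups")
  if (nlevels(droplevels(group)) > 2L)
    stop("Wilcoxon rank-sum association requires exactly two groups")
  g <- droplevels(group)
  # ties force the normal approximation; the switch itself is silent
  suppressWarnings(
    stats::wilcox.test(values[g == levels(g)[1]],
                       values[g == levels(g)[2]])$p.value)
}

#' Enumerate a trait-by-feature association test plan
#'
#' Builds the grid of hypothesis tests run when a set of clinical traits is
#' screened against a set of genomic features (one test per pair), e.g.
#' 5 clinical outcomes against 14 genomic features gives 70 tests.
#'
#' @param outcomes character vector of trait/outcome names
#' @param features character vector of genomic feature names
#' @return a \code{data.frame} with columns \code{outcome} and
#'   \code{feature}, one row per test
#' @export
associationTestGrid <- function(outcomes, features) {
  stopifnot(length(outcomes) >= 1, length(features) >= 1,
            !anyDuplicated(outcomes), !anyDuplicated(features))
  expand.grid(outcome = outcomes, feature = features,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
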