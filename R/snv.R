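#' @include AllClasses.R
NULL

#' Expected mutant-allele fraction of a clonal point mutation
#'
#' Closed-form expectation of the mutant-allele fraction (MAF) under the
#' null hypothesis that the mutation is clonal, i.e. carried by every tumor
#' cell, given tumor purity alpha, the copy state of the locus, and the
#' fraction beta of tumor cells carrying the overlapping CNA. Under the
#' clonal null the point mutation precedes the CNA, so the CNA acts on a
#' mutation-bearing chromosome:
#' \itemize{
#'   \item CN2 (no CNA, beta = 0): alpha / 2
#'   \item CN1, wild-type allele deleted (\code{"mutant_retained"}):
#'     alpha / (2 - alpha beta)
#'   \item CN1, mutant allele deleted (\code{"mutant_lost"}):
#'     alpha (1 - beta) / (2 - alpha beta)
#'   \item LOH, mutant allele duplicated (\code{"mutant_duplicated"}):
#'     alpha (1 + beta) / 2
#'   \item LOH, wild-type allele duplicated (\code{"wildtype_duplicated"}):
#'     alpha (1 - beta) / 2
#' }
#' Amplified (AMP) and homozygously deleted (CN0) loci have no usable
#' clonal-null expectation and must be excluded from testing.
#'
#' @param alpha tumor purity in (0, 1]
#' @param beta fraction of tumor cells carrying the CNA, in [0, 1]
#' @param state copy state at the locus: \code{"CN2"}, \code{"CN1"} or
#'   \code{"LOH"}
#' @param alleleConfig which allele the CNA acted on (see above);
#'   \code{"none"} is accepted for CN2, where it is irrelevant
#' @return expected MAF in [0, 1]
#' @examples
#' expectedMaf(0.5, 0.5, "CN1", "mutant_retained")     # 0.2857...
#' expectedMaf(0.5, 0.5, "LOH", "mutant_duplicated")   # 0.375
#' @export
expectedMaf <- function(alpha, beta, state, alleleConfig = "none") {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            alpha > 0, alpha <= 1, beta >= 0, beta <= 1)
  if (state %in% c("AMP", "CN0"))
    stop("no clonal-null MAF exists for state ", state,
         "; mark the SNV as excluded")
  state <- match.arg(state, c("CN2", "CN1", "LOH"))
  if (state == "CN2" || beta == 0)
    return(alpha / 2)
  cfgs <- switch(state,
    CN1 = c("mutant_retained", "mutant_lost"),
    LOH = c("mutant_duplicated", "wildtype_duplicated"))
  if (!alleleConfig %in% cfgs)
    stop("alleleConfig must be one of ", paste(cfgs, collapse = ", "),
         " for state ", state)
  switch(alleleConfig,
    mutant_retained = alpha / (2 - alpha * beta),
    mutant_lost = alpha * (1 - beta) / (2 - alpha * beta),
    mutant_duplicated = alpha * (1 + beta) / 2,
    wildtype_duplicated = alpha * (1 - beta) / 2)
}

#' Exact binomial test of the clonal null for one SNV
#'
#' One-sided lower-tail exact binomial p-value P(X <= altCount | depth,
#' expectedMaf): subclonality can only depress the observed mutant-allele
#' fraction below the clonal expectation, so small p-values support a
#' subclonal mutation. The test is uniform-or-conservative under the
#' clonal null (conservative because of binomial discreteness).
#'
#' @param altCount observed mutant read count
#' @param depth total read depth
#' @param expectedMaf clonal-null expected MAF in (0, 1), from
#'   \code{\link{expectedMaf}}
#' @return the lower-tail p-value
#' @examples
#' clonalityTest(0, 30, 0.25)  # 0.75^30
#' @export
clonalityTest <- function(altCount, depth, expectedMaf) {
  stopifnot(all(altCount >= 0), all(depth >= 1), all(altCount <= depth))
  if (any(expectedMaf <= 0 | expectedMaf >= 1))
    stop("expected MAF of 0 or 1 gives a degenerate clonality model")
  stats::pbinom(altCount, depth, expectedMaf)
}

#' Call clonality for somatic SNVs of one sample
#'
#' Applies the clonal-null MAF model and exact binomial test to each SNV.
#' Mutations in amplified (AMP) or homozygously deleted (CN0) regions are
#' excluded: their absolute copy number and subclonality cannot be resolved.
#' When the allele configuration of an SNV in a CNA region is unknown, both
#' configurations are tested and the larger p-value is kept (conservative:
#' an SNV is only called subclonal if it is subclonal under every
#' configuration). SNVs overlapping CNAs with an unassigned cell fraction
#' are tested with beta = 0 and flagged in \code{betaImputed}.
#'
#' @param snvTable a \code{data.frame} with columns \code{depth},
#'   \code{altCount}, \code{segmentState} and \code{beta} (tumor-cell CNA
#'   fraction; may be \code{NA}), optionally \code{alleleConfig}
#' @param alpha tumor purity, or a \linkS4class{PurityEstimate}
#' @param alphaCutoff p-value threshold below which an SNV is called
#'   subclonal
#' @return the table with columns \code{expectedMaf}, \code{pClonal},
#'   \code{clonality} and \code{betaImputed} added
#' @export
callSnvClonality <- function(snvTable, alpha, alphaCutoff = 0.05) {
  if (is(alpha, "PurityEstimate")) alpha <- alpha@alpha
  stopifnot(is.data.frame(snvTable), alpha > 0, alpha <= 1)
  need <- c("depth", "altCount", "segmentState", "beta")
  miss <- setdiff(need, names(snvTable))
  if (length(miss))
    stop("snvTable lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(snvTable)
  cfg <- snvTable$alleleConfig %||% rep(NA_character_, n)
  emaf <- pp <- rep(NA_real_, n)
  lab <- rep(NA_character_, n)
  imputed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    st <- snvTable$segmentState[i]
    if (st %in% c("AMP", "CN0")) {
      lab[i] <- "excluded"
      next
    }
    b <- snvTable$beta[i]
    if (!is.finite(b)) {
      b <- 0
      imputed[i] <- TRUE
    }
    ci <- cfg[i]
    if (st == "CN2" || b == 0) {
      m <- expectedMaf(alpha, 0, "CN2")
      p <- clonalityTest(snvTable$altCount[i], snvTable$depth[i], m)
    } else if (!is.na(ci) && ci != "none") {
      m <- expectedMaf(alpha, b, st, ci)
      p <- if (m <= 0 || m >= 1) NA_real_ else
        clonalityTest(snvTable$altCount[i], snvTable$depth[i], m)
    } else {
      # unknown configuration: test both, keep the larger p
      cfgs <- if (st == "CN1") c("mutant_retained", "mutant_lost")
              else c("mutant_duplicated", "wildtype_duplicated")
      ms <- vapply(cfgs, function(cc) expectedMaf(alpha, b, st, cc),
                   numeric(1))
      ps <- vapply(ms, function(m) {
        if (m <= 0 || m >= 1) NA_real_
        else clonalityTest(snvTable$altCount[i], snvTable$depth[i], m)
      }, numeric(1))
      if (all(is.na(ps))) {
        lab[i] <- "excluded"
        next
      }
      keep <- which.max(ps)
      m <- ms[keep]
      p <- ps[keep]
    }
    if (!is.finite(p)) {
      lab[i] <- "excluded"
      next
    }
    emaf[i] <- m
    pp[i] <- p
    lab[i] <- if (p < alphaCutoff) "subclonal" else "clonal"
  }
  snvTable$expectedMaf <- emaf
  snvTable$pClonal <- pp
  snvTable$clonality <- lab
  snvTable$betaImputed <- imputed
  snvTable
}

#' Fraction of subclonal mutations
#'
#' FSM = n_subclonal / (n_clonal + n_subclonal) over a set of clonality
#' calls; excluded calls are ignored.
#'
#' @param calls character vector of \code{"clonal"}, \code{"subclonal"},
#'   \code{"excluded"}
#' @return the fraction in [0, 1], or \code{NA} if no call was classified
#' @examples
#' fsm(c("clonal", "subclonal", "subclonal", "clonal"))  # 0.5
#' @export
fsm <- function(calls) {
  stopifnot(all(calls %in% SNV_CLONALITY_LEVELS))
  nc <- sum(calls == "clonal")
  ns <- sum(calls == "subclonal")
  if (nc + ns == 0L) return(NA_real_)
  ns / (nc + ns)
}

#' Fisher's exact test of a gene's FSM against the background
#'
#' Tests whether the clonal/subclonal composition of one gene's mutations
#' differs from the pooled background using the exact hypergeometric
#' distribution of the 2x2 table (gene vs background, clonal vs subclonal).
#'
#' @param geneCounts integer vector \code{c(nClonal, nSubclonal)} for the
#'   gene
#' @param backgroundCounts integer vector \code{c(nClonal, nSubclonal)} for
#'   the background
#' @return two-sided Fisher's exact p-value
#' @examples
#' fsmGeneTest(c(5, 5), c(50, 50))  # 1
#' @export
fsmGeneTest <- function(geneCounts, backgroundCounts) {
  stopifnot(length(geneCounts) == 2, length(backgroundCounts) == 2,
            all(geneCounts >= 0), all(backgroundCounts >= 0))
  tab <- rbind(geneCounts, backgroundCounts)
  if (sum(tab) == 0) stop("empty 2x2 table")
  stats::fisher.test(tab)$p.value
}

#' 2x2 enrichment comparison of two groups
#'
#' Compares the rate of a binary feature (e.g. APOBEC membership) between
#' two mutation groups (e.g. subclonal vs clonal) by Fisher's exact test,
#' and reports both group fractions.
#'
#' @param groupA,groupB integer vectors \code{c(nWithFeature,
#'   nWithoutFeature)} for the two groups
#' @return a list with \code{fractionA}, \code{fractionB}, \code{p} and
#'   the odds ratio estimate \code{oddsRatio}
#' @examples
#' enrichment2x2(c(13, 87), c(8, 92))
#' @export
enrichment2x2 <- function(groupA, groupB) {
  stopifnot(length(groupA) == 2, length(groupB) == 2,
            all(groupA >= 0), all(groupB >= 0))
  tab <- rbind(groupA, groupB)
  if (sum(tab) == 0) stop("empty 2x2 table")
  ft <- stats::fisher.test(tab)
  list(fractionA = groupA[1] / sum(groupA),
       fractionB = groupB[1] / sum(groupB),
       p = ft$p.value,
       oddsRatio = unname(ft$estimate))
}

#' Per-gene FSM summaries with tests against the pooled background
#'
#' Aggregates clonality calls by gene, computes each gene's FSM, and tests
#' it against the pooled counts of all other genes by Fisher's exact test.
#' Excluded calls are dropped first.
#'
#' @param gene character vector of gene symbols, one per mutation
#' @param calls matching clonality calls
#' @param minMutations genes with fewer classified mutations are dropped
#' @return a \code{data.frame} with columns \code{gene}, \code{nClonal},
#'   \code{nSubclonal}, \code{fsm}, \code{p}
#' @export
fsmByGene <- function(gene, calls, minMutations = 1L) {
  stopifnot(length(gene) == length(calls))
  keep <- calls %in% c("clonal", "subclonal") & !is.na(gene) & gene != ""
  gene <- gene[keep]
  calls <- calls[keep]
  if (!length(gene))
    return(data.frame(gene = character(), nClonal = integer(),
                      nSubclonal = integer(), fsm = numeric(),
                      p = numeric()))
  tab <- table(gene, factor(calls, levels = c("clonal", "subclonal")))
  nc <- as.integer(tab[, "clonal"])
  ns <- as.integer(tab[, "subclonal"])
  keepG <- (nc + ns) >= minMutations
  genes <- rownames(tab)[keepG]
  nc <- nc[keepG]
  ns <- ns[keepG]
  totC <- sum(calls == "clonal")
  totS <- sum(calls == "subclonal")
  p <- mapply(function(a, b)
    fsmGeneTest(c(a, b), c(totC - a, totS - b)), nc, ns)
  data.frame(gene = genes, nClonal = nc, nSubclonal = ns,
             fsm = ns / (nc + ns), p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the SNV clonality stage on a TumorSample
#'
#' Inherits each SNV's beta from the overlapping segment's estimated cell
#' fraction (beta = c / alpha), then calls clonality for every SNV via
#' \code{\link{callSnvClonality}} using the sample's purity estimate.
#'
#' @param sample a \linkS4class{TumorSample} processed by
#'   \code{\link{analyzeCna}} (or carrying a purity estimate)
#' @param alphaCutoff p-value threshold for a subclonal call
#' @return the sample with SNV metadata columns \code{expectedMaf},
#'   \code{pClonal}, \code{clonality}, \code{betaImputed} filled in
#' @export
analyzeSnvClonality <- function(sample, alphaCutoff = 0.05) {
  stopifnot(is(sample, "TumorSample"))
  if (is.null(sample@purity))
    stop("sample has no purity estimate; run analyzeCna() first")
  a <- sample@purity@alpha
  snv <- sample@snvs
  seg <- sample@segments
  mc <- as.data.frame(S4Vectors::mcols(snv))
  if (is.null(mc$segmentState) || is.null(mc$beta)) {
    hit <- GenomicRanges::findOverlaps(snv, seg, select = "first")
    segState <- S4Vectors::mcols(seg)$state[hit]
    segState[is.na(segState)] <- "CN2"
    cf <- S4Vectors::mcols(seg)$cellFraction
    beta <- if (is.null(cf)) rep(NA_real_, length(snv)) else
      pmin(cf[hit] / a, 1)
    beta[segState == "CN2"] <- 0
    mc$segmentState <- segState
    mc$beta <- beta
  }
  out <- callSnvClonality(mc, a, alphaCutoff = alphaCutoff)
  S4Vectors::mcols(sample@snvs) <- S4Vectors::DataFrame(out)
  sample
}
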