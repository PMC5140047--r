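#' @include AllClasses.R
NULL

#' Covariate-adjusted association of one CpG probe with a mutation trait
#'
#' Ordinary least-squares fit of the mutation-signature trait on the probe's
#' methylation level plus covariates. The reported effect is the methylation
#' coefficient (positive effect = higher methylation, higher trait value)
#' with its two-sided t-test p-value. Samples with missing values are
#' dropped listwise.
#'
#' @param methylation numeric vector of beta values across samples
#' @param trait numeric trait vector (e.g. TNSM, FT, FA)
#' @param covariates optional \code{data.frame} of adjustment covariates
#'   (categorical covariates as factors)
#' @return a list with \code{effect}, \code{p} and \code{n} (samples used);
#'   when the design is collinear in methylation, \code{effect} and
#'   \code{p} are \code{NA} and \code{skipped} gives the reason
#' @examples
#' probeAssociation(c(0, 1, 2, 3), c(1, 2, 4, 3))  # slope 0.8
#' @export
probeAssociation <- function(methylation, trait, covariates = NULL) {
  stopifnot(length(methylation) == length(trait))
  df <- data.frame(.trait = trait, .meth = methylation)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(trait))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 2L)
    stop("too few complete observations for the association model")
  fit <- stats::lm(.trait ~ ., data = df)
  co <- summary(fit)$coefficients
  if (!".meth" %in% rownames(co) || is.na(stats::coef(fit)[".meth"]))
    return(list(effect = NA_real_, p = NA_real_, n = nrow(df),
                skipped = "collinear design"))
  list(effect = unname(co[".meth", "Estimate"]),
       p = unname(co[".meth", "Pr(>|t|)"]),
       n = nrow(df))
}

#' Genome-wide probe-by-probe methylation association
#'
#' Runs \code{\link{probeAssociation}} for every probe of a methylation
#' matrix against one trait, flags significance at the Bonferroni threshold
#' (alpha divided by the number of probes actually tested, taken from the
#' input, never hard-coded), and attaches probe annotations when supplied.
#'
#' @param methylation numeric matrix, probes x samples, with probe ids as
#'   row names
#' @param trait numeric trait vector, one value per sample (column)
#' @param covariates optional covariate \code{data.frame}, samples in rows
#' @param annotation optional \code{data.frame} with columns \code{probe},
#'   \code{cgi} (CGI / nonCGI / open-sea) and \code{region} (promoter /
#'   body / 3'UTR / intergenic)
#' @param alphaLevel family-wise error rate for the Bonferroni threshold
#' @param trait.name label recorded in the result
#' @return a \code{data.frame} with one row per probe: \code{probe},
#'   \code{trait}, \code{effect}, \code{p}, \code{significant}, and the
#'   annotation columns when given. The Bonferroni threshold used is
#'   stored in \code{attr(, "threshold")}.
#' @export
methylationAssociation <- function(methylation, trait, covariates = NULL,
                                   annotation = NULL, alphaLevel = 0.05,
                                   trait.name = "trait") {
  stopifnot(is.matrix(methylation), ncol(methylation) == length(trait))
  probesIds <- rownames(methylation) %||% as.character(seq_len(nrow(methylation)))
  res <- vapply(seq_len(nrow(methylation)), function(i) {
    a <- probeAssociation(methylation[i, ], trait, covariates)
    c(a$effect, a$p)
  }, numeric(2))
  out <- data.frame(probe = probesIds, trait = trait.name,
                    effect = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE)
  thr <- bonferroniThreshold(sum(!is.na(out$p)), alphaLevel)
  out$significant <- !is.na(out$p) & out$p < thr
  if (!is.null(annotation)) {
    m <- match(out$probe, annotation$probe)
    out$cgi <- annotation$cgi[m]
    out$region <- annotation$region[m]
  }
  attr(out, "threshold") <- thr
  out
}

#' Bonferroni significance threshold
#'
#' @param nProbes number of tests performed
#' @param alphaLevel family-wise error rate
#' @return \code{alphaLevel / nProbes}
#' @examples
#' bonferroniThreshold(338730, 0.05)  # 1.476e-07
#' @export
bonferroniThreshold <- function(nProbes, alphaLevel = 0.05) {
  stopifnot(nProbes >= 1, alphaLevel > 0, alphaLevel <= 1)
  alphaLevel / nProbes
}

#' Enrichment fold change of significant probes in one annotation category
#'
#' The category's significant-probe rate divided by the overall rate:
#' fold = (kCat/nCat) / (kAll/nAll). Full precision is retained; round for
#' display only.
#'
#' @param kCat,nCat significant and total probes in the category
#' @param kAll,nAll significant and total probes overall
#' @return a list with \code{fold}, \code{fractionCat}, \code{fractionAll};
#'   \code{fold} is \code{NA} when \code{kAll} is 0
#' @examples
#' enrichmentFoldChange(12339, 110542, 22337, 338739)  # fold 1.69...
#' @export
enrichmentFoldChange <- function(kCat, nCat, kAll, nAll) {
  stopifnot(nCat > 0, nAll > 0, kCat >= 0, kAll >= 0,
            kCat <= nCat, kAll <= nAll)
  fCat <- kCat / nCat
  fAll <- kAll / nAll
  list(fold = if (kAll == 0) NA_real_ else fCat / fAll,
       fractionCat = fCat, fractionAll = fAll)
}

#' Fraction of significant probes in a category with positive effects
#'
#' @param associations result of \code{\link{methylationAssociation}}
#' @param category value of the annotation column to restrict to, or
#'   \code{NULL} for all probes
#' @param by annotation column name (\code{"cgi"} or \code{"region"})
#' @return share of significant (restricted) probes with effect > 0;
#'   \code{NA} when none is significant
#' @export
fractionPositive <- function(associations, category = NULL, by = "cgi") {
  sel <- associations$significant
  if (!is.null(category)) {
    if (!by %in% names(associations))
      stop("no annotation column '", by, "' in the association table")
    sel <- sel & !is.na(associations[[by]]) & associations[[by]] == category
  }
  if (!any(sel, na.rm = TRUE)) return(NA_real_)
  mean(associations$effect[which(sel)] > 0)
}

#' Per-category enrichment summary of an association table
#'
#' For every level of an annotation column, computes the significant-probe
#' enrichment fold change relative to all probes and the fraction of
#' positive associations among the category's significant probes.
#'
#' @inheritParams fractionPositive
#' @return a \code{data.frame} with columns \code{category}, \code{kCat},
#'   \code{nCat}, \code{kAll}, \code{nAll}, \code{fold},
#'   \code{fracPositive}
#' @export
categoryEnrichment <- function(associations, by = "cgi") {
  if (!by %in% names(associations))
    stop("no annotation column '", by, "' in the association table")
  cats <- sort(unique(stats::na.omit(associations[[by]])))
  kAll <- sum(associations$significant, na.rm = TRUE)
  nAll <- sum(!is.na(associations$p))
  rows <- lapply(cats, function(cc) {
    inCat <- !is.na(associations[[by]]) & associations[[by]] == cc
    kCat <- sum(associations$significant[inCat], na.rm = TRUE)
    nCat <- sum(inCat & !is.na(associations$p))
    e <- enrichmentFoldChange(kCat, nCat, kAll, nAll)
    data.frame(category = cc, kCat = kCat, nCat = nCat,
               kAll = kAll, nAll = nAll, fold = e$fold,
               fracPositive = fractionPositive(associations, cc, by),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Standard step-up procedure controlling the false discovery rate at
#' level q, via \code{stats::p.adjust}.
#'
#' @param p vector of p-values in (0, 1]
#' @param q target FDR
#' @return logical flags, \code{TRUE} for discoveries
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
#' @export
benjaminiHochberg <- function(p, q = 0.05) {
  stopifnot(all(p > 0 & p <= 1), q > 0, q < 1)
  stats::p.adjust(p, method = "BH") <= q
}
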