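#' @include AllClasses.R
NULL

#' Fold B-allele frequencies about 0.5
#'
#' Removes the arbitrary A/B allele labeling by mapping every BAF value v to
#' min(v, 1 - v), so both mixture components of an allelic-imbalance signal
#' fold onto one peak in [0, 0.5].
#'
#' @param baf numeric vector of BAF values in [0, 1]
#' @return numeric vector in [0, 0.5]
#' @examples
#' foldBaf(c(0.2, 0.8))  # both 0.2
#' @export
foldBaf <- function(baf) {
  if (any(!is.finite(baf)) || any(baf < 0 | baf > 1))
    stop("BAF values must lie in [0, 1]")
  pmin(baf, 1 - baf)
}

#' Fit the two BAF peaks of a deletion or LOH segment by EM
#'
#' Fits a two-component Gaussian mixture to heterozygous-probe BAFs,
#' constrained symmetric about 0.5 with a shared variance: components
#' N(mu, sd^2) and N(1 - mu, sd^2) with mixing weight w. The constraint
#' reflects the geometry of heterozygous probes, whose two allele labelings
#' are exchangeable, and makes the fit identifiable. The EM iteration is
#' initialized from the 10th percentile of the folded BAFs and the observed
#' log-likelihood is non-decreasing across iterations.
#'
#' @param baf numeric vector of BAF values in [0, 1]
#' @param maxIter maximum EM iterations
#' @param tol relative convergence tolerance on the log-likelihood
#'   increment
#' @param minProbes minimum number of probes required for a fit
#' @param degenerateSep peak separation below which the segment is flagged
#'   as degenerate (no resolvable allelic imbalance)
#' @return a list with elements \code{ok} (logical; \code{FALSE} with a
#'   \code{reason} when there are fewer than \code{minProbes} values),
#'   \code{mu1} and \code{mu2} (peak positions, \code{mu1 <= 0.5 <= mu2}),
#'   \code{weight} (mixing weight of the lower component), \code{sd}
#'   (shared noise standard deviation), \code{logLik} (per-iteration
#'   log-likelihood trace), \code{converged}, \code{nIter} and
#'   \code{degenerate}
#' @export
fitBafPeaks <- function(baf, maxIter = 1000L, tol = 1e-7, minProbes = 50L,
                        degenerateSep = 0.02) {
  if (any(!is.finite(baf)) || any(baf < 0 | baf > 1))
    stop("BAF values must lie in [0, 1]")
  n <- length(baf)
  if (n < minProbes)
    return(list(ok = FALSE, reason = "too_few_probes", n = n))
  x <- baf
  folded <- foldBaf(x)
  mu <- min(unname(stats::quantile(folded, 0.1)), 0.5)
  sd <- max(stats::sd(folded), 0.01)
  w <- 0.5
  sdFloor <- 1e-4
  ll <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    d1 <- w * stats::dnorm(x, mu, sd)
    d2 <- (1 - w) * stats::dnorm(x, 1 - mu, sd)
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- c(ll, sum(log(tot)))
    if (iter > 1 && ll[iter] - ll[iter - 1] < tol * (1 + abs(ll[iter]))) {
      converged <- TRUE
      break
    }
    r <- d1 / tot
    muNew <- sum(r * x + (1 - r) * (1 - x)) / n
    if (muNew > 0.5) {
      muNew <- 1 - muNew
      r <- 1 - r
    }
    varNew <- sum(r * (x - muNew)^2 + (1 - r) * (x - (1 - muNew))^2) / n
    mu <- muNew
    sd <- max(sqrt(varNew), sdFloor)
    w <- mean(r)
  }
  if (!converged)
    warning("EM did not converge within ", maxIter,
            " iterations; returning best fit so far")
  list(ok = TRUE, mu1 = mu, mu2 = 1 - mu, weight = w, sd = sd,
       logLik = ll, converged = converged, nIter = length(ll),
       degenerate = (1 - 2 * mu) < degenerateSep, n = n)
}

#' Invert BAF peak positions into a CNA cell fraction
#'
#' For a hemizygous deletion carried by a fraction c of all cells, the
#' heterozygous-probe BAF peaks sit at (1-c)/(2-c) and 1/(2-c), so
#' c = 2d/(1+d) with d = mu2 - mu1. For copy-neutral LOH the peaks sit at
#' (1-c)/2 and (1+c)/2, so c = d. Homozygous deletions leave no
#' heterozygous tumor signal (the apparent peak separation is 0 and the
#' same inversion returns 0); amplifications are not supported.
#'
#' @param mu1,mu2 fitted peak positions with \code{mu1 <= mu2}
#' @param state copy state, one of \code{"CN1"}, \code{"LOH"}, \code{"CN0"}
#' @return the cell fraction c in [0, 1] (fraction of all cells carrying
#'   the CNA)
#' @examples
#' cellFractionFromPeaks(1/3, 2/3, "CN1")  # 0.5
#' cellFractionFromPeaks(0.4, 0.6, "LOH")  # 0.2
#' @export
cellFractionFromPeaks <- function(mu1, mu2, state) {
  state <- match.arg(state, c("CN1", "LOH", "CN0"))
  stopifnot(is.numeric(mu1), is.numeric(mu2), length(mu1) == 1,
            length(mu2) == 1, mu1 <= mu2)
  d <- mu2 - mu1
  c <- switch(state,
    CN1 = 2 * d / (1 + d),
    LOH = d,
    CN0 = 0)
  min(max(c, 0), 1)
}

# Local maxima of a density grid with basin mass attribution: each grid
# point is assigned to the nearest peak by descending to the separating
# local minima; peaks whose basin carries less than minShare of the total
# mass are discarded as noise.
densityPeakLocations <- function(dens, minShare = 0.05) {
  y <- dens$y
  x <- dens$x
  n <- length(y)
  isMax <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) isMax <- c(1L, isMax)
  if (y[n] > y[n - 1]) isMax <- c(isMax, n)
  if (!length(isMax)) isMax <- which.max(y)
  if (length(isMax) == 1L) return(x[isMax])
  # separating minima between consecutive peaks
  cuts <- vapply(seq_len(length(isMax) - 1L), function(i) {
    seg <- isMax[i]:isMax[i + 1L]
    seg[which.min(y[seg])]
  }, integer(1))
  bounds <- c(1L, cuts, n)
  mass <- vapply(seq_along(isMax), function(i)
    sum(y[bounds[i]:bounds[i + 1L]]), numeric(1))
  share <- mass / sum(y)
  keep <- share >= minShare
  if (!any(keep)) keep <- which.max(share)
  sort(x[isMax[keep]])
}

#' Estimate tumor purity from per-CNA cell fractions
#'
#' Computes a Gaussian kernel density of the per-CNA cell fractions (pi),
#' extracts its local maxima, and interprets each sufficiently supported
#' peak as one clone. The rightmost peak is the primary clone and its
#' location is the tumor purity estimate.
#'
#' @param piValues numeric vector of per-CNA cell fractions in [0, 1]
#' @param bandwidthRule bandwidth selector passed to
#'   \code{\link[stats]{density}} (default \code{"nrd0"}, Silverman's rule)
#' @param minPeakShare minimum share of total density mass a peak's basin
#'   must carry to count as a clone (guards against noise peaks inflating
#'   the purity estimate)
#' @return a \linkS4class{PurityEstimate}
#' @examples
#' estimatePurity(c(0.29, 0.3, 0.31, 0.69, 0.7, 0.71))
#' @export
estimatePurity <- function(piValues, bandwidthRule = "nrd0",
                           minPeakShare = 0.05) {
  piValues <- piValues[is.finite(piValues)]
  if (!length(piValues))
    stop("no usable CNAs: cannot estimate purity from an empty pi list")
  stopifnot(all(piValues >= 0 & piValues <= 1))
  if (length(piValues) == 1L || diff(range(piValues)) < 1e-8) {
    a <- min(max(mean(piValues), 1e-6), 1)
    return(new("PurityEstimate", alpha = a, piValues = piValues,
               densityPeaks = a, bandwidth = 0))
  }
  dens <- stats::density(piValues, bw = bandwidthRule, kernel = "gaussian")
  peaks <- densityPeakLocations(dens, minShare = minPeakShare)
  peaks <- pmin(pmax(peaks, 1e-6), 1)
  new("PurityEstimate", alpha = max(peaks), piValues = piValues,
      densityPeaks = peaks, bandwidth = dens$bw)
}

#' Classify a CNA as clonal or subclonal
#'
#' A CNA is clonal when its cell fraction reaches the tumor purity up to a
#' relative tolerance: clonal iff c >= (1 - relTol) * alpha. The default
#' tolerance of 0.1 absorbs the estimation noise of the EM peak fit and of
#' the purity estimate.
#'
#' @param cellFraction per-CNA cell fraction(s) c
#' @param alpha tumor purity, or a \linkS4class{PurityEstimate}
#' @param relTol relative tolerance of the clonality band
#' @return character vector of \code{"clonal"}/\code{"subclonal"}
#'   (\code{"unassigned"} for \code{NA} cell fractions)
#' @examples
#' classifyCnaClonality(c(0.58, 0.30), alpha = 0.6, relTol = 0.1)
#' @export
classifyCnaClonality <- function(cellFraction, alpha, relTol = 0.1) {
  if (is(alpha, "PurityEstimate")) alpha <- alpha@alpha
  stopifnot(length(alpha) == 1, alpha > 0, alpha <= 1, relTol >= 0)
  out <- ifelse(cellFraction >= (1 - relTol) * alpha, "clonal", "subclonal")
  out[!is.finite(cellFraction)] <- "unassigned"
  out
}

#' Assign a copy state from the tumor/normal read ratio and BAF evidence
#'
#' The sequencing read-depth ratio between tumor and matched germline DNA
#' determines the total copy number while the fitted BAF peaks provide the
#' allelic-imbalance evidence: a ratio near zero is a homozygous deletion
#' (CN0); a reduced ratio with allelic imbalance is a hemizygous deletion
#' (CN1); a ratio near 1 is copy-neutral LOH when imbalanced and CN2
#' otherwise; an elevated ratio is an amplification (AMP).
#'
#' @param readRatio tumor/normal read-depth ratio (> 0)
#' @param mu1,mu2 fitted BAF peak positions
#' @param lowThreshold ratio below which (and above \code{zeroThreshold})
#'   a deletion is called
#' @param highThreshold ratio above which an amplification is called
#' @param zeroThreshold ratio below which a homozygous deletion is called
#' @param imbalanceThreshold minimum peak separation \code{mu2 - mu1}
#'   counting as allelic imbalance
#' @return one of \code{"CN0"}, \code{"CN1"}, \code{"CN2"}, \code{"LOH"},
#'   \code{"AMP"}
#' @examples
#' assignCopyState(1.0, 0.5, 0.5)   # CN2
#' assignCopyState(1.0, 0.3, 0.7)   # LOH
#' assignCopyState(0.75, 0.35, 0.65)  # CN1
#' @export
assignCopyState <- function(readRatio, mu1, mu2,
                            lowThreshold = 0.9, highThreshold = 1.1,
                            zeroThreshold = 0.25,
                            imbalanceThreshold = 0.1) {
  stopifnot(length(readRatio) == 1)
  if (!is.finite(readRatio) || readRatio <= 0)
    stop("read ratio must be positive")
  imbalanced <- (mu2 - mu1) >= imbalanceThreshold
  if (readRatio < zeroThreshold) return("CN0")
  if (readRatio < lowThreshold) return(if (imbalanced) "CN1" else "CN2")
  if (readRatio <= highThreshold) return(if (imbalanced) "LOH" else "CN2")
  "AMP"
}

#' Run the CNA clonality and purity stage on one sample
#'
#' For every deletion (CN1) and LOH segment with enough heterozygous
#' probes, fits the symmetric BAF mixture by EM, inverts the peaks into a
#' cell fraction, estimates tumor purity as the rightmost clone peak of the
#' cell-fraction density, and classifies each CNA as clonal or subclonal.
#' CN2 segments carry no CNA, CN0 segments contribute no heterozygous
#' tumor signal, and amplifications are excluded because of their large
#' amplitude variability; none of these contribute to the purity estimate.
#'
#' @param sample a \linkS4class{TumorSample} whose \code{probes} carry a
#'   \code{baf} column and a \code{segmentId} column (or are located by
#'   overlap with the segments)
#' @param minProbes minimum heterozygous probes per segment for a fit
#' @param relTol clonality tolerance, see \code{\link{classifyCnaClonality}}
#' @param minPeakShare see \code{\link{estimatePurity}}
#' @return the sample with segment metadata columns \code{mu1}, \code{mu2},
#'   \code{cellFraction}, \code{clonality} filled in and \code{purity} set
#' @export
analyzeCna <- function(sample, minProbes = 50L, relTol = 0.1,
                       minPeakShare = 0.05) {
  stopifnot(is(sample, "TumorSample"))
  seg <- sample@segments
  prb <- sample@probes
  nSeg <- length(seg)
  mc <- S4Vectors::mcols(seg)
  if (is.null(mc$segmentId)) mc$segmentId <- seq_len(nSeg)
  if (!is.null(S4Vectors::mcols(prb)$segmentId)) {
    probeSeg <- match(S4Vectors::mcols(prb)$segmentId, mc$segmentId)
  } else {
    hits <- GenomicRanges::findOverlaps(prb, seg, select = "first")
    probeSeg <- hits
  }
  mu1 <- mu2 <- cf <- rep(NA_real_, nSeg)
  clon <- rep("unassigned", nSeg)
  for (i in seq_len(nSeg)) {
    st <- mc$state[i]
    if (!st %in% c("CN1", "LOH")) next
    baf <- S4Vectors::mcols(prb)$baf[which(probeSeg == i)]
    fit <- fitBafPeaks(baf, minProbes = minProbes)
    if (!isTRUE(fit$ok)) next
    mu1[i] <- fit$mu1
    mu2[i] <- fit$mu2
    cf[i] <- cellFractionFromPeaks(fit$mu1, fit$mu2, st)
  }
  mc$mu1 <- mu1
  mc$mu2 <- mu2
  mc$cellFraction <- cf
  usable <- cf[is.finite(cf)]
  if (length(usable)) {
    pur <- estimatePurity(usable, minPeakShare = minPeakShare)
    clon <- classifyCnaClonality(cf, pur, relTol = relTol)
    sample@purity <- pur
  }
  mc$clonality <- clon
  S4Vectors::mcols(sample@segments) <- mc
  validObject(sample)
  sample
}
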