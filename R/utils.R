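#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' User-facing tables carry 1-based inclusive coordinates (the convention of
#' MAF-like mutation tables and \code{GRanges}); BED-like exchange uses
#' 0-based half-open. These helpers convert a start/end pair between the two
#' conventions and are exact inverses of each other.
#'
#' @param start,end integer vectors of interval bounds
#' @return a list with components \code{start} and \code{end}
#' @examples
#' toZeroBased(1, 10)   # list(start = 0, end = 10)
#' toOneBased(0, 10)    # list(start = 1, end = 10)
#' @export
toZeroBased <- function(start, end) {
  stopifnot(all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname toZeroBased
#' @export
toOneBased <- function(start, end) {
  stopifnot(all(end >= start))
  list(start = start + 1L, end = end)
}

# Truncated-normal draws on [0, 1] by inverse-CDF; exact truncation rather
# than clamping so noise never piles mass onto the boundaries.
rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Deterministic per-sample seed derived from the config seed; kept within
# 32-bit integer range.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
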