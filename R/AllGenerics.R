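#' @include AllClasses.R
NULL

#' Accessors for clonescape classes
#'
#' @param object,x a \linkS4class{TumorSample}, \linkS4class{PurityEstimate},
#'   \linkS4class{GroundTruth} or \linkS4class{SignatureSummary}
#' @param value replacement value
#'
#' @return \code{sampleId} the sample identifier; \code{segments},
#'   \code{probes} and \code{snvs} the corresponding \code{GRanges};
#'   \code{purity} the \linkS4class{PurityEstimate} (or \code{NULL});
#'   \code{alpha} the purity point estimate; \code{piValues} the per-CNA
#'   cell fractions; \code{densityPeaks} the retained clone peak locations.
#'
#' @name accessors
#' @aliases sampleId segments probes snvs purity purity<- alpha piValues
#'   densityPeaks
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))
#' @rdname accessors
#' @export
setGeneric("snvs", function(object) standardGeneric("snvs"))
#' @rdname accessors
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))
#' @rdname accessors
#' @export
setGeneric("purity<-", function(object, value) standardGeneric("purity<-"))
#' @rdname accessors
#' @export
setGeneric("alpha", function(object) standardGeneric("alpha"))
#' @rdname accessors
#' @export
setGeneric("piValues", function(object) standardGeneric("piValues"))
#' @rdname accessors
#' @export
setGeneric("densityPeaks", function(object) standardGeneric("densityPeaks"))

#' @rdname accessors
setMethod("sampleId", "TumorSample", function(object) object@sampleId)
#' @rdname accessors
setMethod("segments", "TumorSample", function(object) object@segments)
#' @rdname accessors
setMethod("probes", "TumorSample", function(object) object@probes)
#' @rdname accessors
setMethod("snvs", "TumorSample", function(object) object@snvs)
#' @rdname accessors
setMethod("purity", "TumorSample", function(object) object@purity)
#' @rdname accessors
setMethod("purity<-", "TumorSample", function(object, value) {
  object@purity <- value
  validObject(object)
  object
})
#' @rdname accessors
setMethod("sampleId", "GroundTruth", function(object) object@sampleId)
#' @rdname accessors
setMethod("sampleId", "SignatureSummary", function(object) object@sampleId)
#' @rdname accessors
setMethod("alpha", "PurityEstimate", function(object) object@alpha)
#' @rdname accessors
setMethod("piValues", "PurityEstimate", function(object) object@piValues)
#' @rdname accessors
setMethod("densityPeaks", "PurityEstimate", function(object) object@densityPeaks)
#' @rdname accessors
setMethod("alpha", "TumorSample", function(object) {
  if (is.null(object@purity)) NA_real_ else object@purity@alpha
})

setMethod("show", "PurityEstimate", function(object) {
  cat("PurityEstimate\n")
  cat(sprintf("  alpha (tumor purity): %.4f\n", object@alpha))
  cat(sprintf("  clones (density peaks): %s\n",
              paste(sprintf("%.3f", object@densityPeaks), collapse = ", ")))
  cat(sprintf("  based on %d CNA cell fractions, bandwidth %.4g\n",
              length(object@piValues), object@bandwidth))
  invisible(NULL)
})

setMethod("show", "TumorSample", function(object) {
  cat("TumorSample:", object@sampleId, "\n")
  cat(sprintf("  %d segments, %d probes, %d SNVs\n",
              length(object@segments), length(object@probes),
              length(object@snvs)))
  if (!is.null(object@purity))
    cat(sprintf("  purity: %.4f\n", object@purity@alpha))
  else cat("  purity: not estimated\n")
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d samples, purity in [%.2f, %.2f], seed %d\n",
              object@nSamples, object@purityRange[1], object@purityRange[2],
              object@seed))
  cat(sprintf("  %d segments/sample (%d probes each, BAF noise sd %.3f)\n",
              object@nSegments, object@probesPerSegment, object@bafNoiseSd))
  cat(sprintf("  %d SNVs/sample at mean depth %.0f, P(subclonal) = %.2f\n",
              object@nSnvs, object@meanDepth, object@subclonalSnvProb))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", object@sampleId, "\n")
  cat(sprintf("  true purity %.4f; %d segments, %d SNVs\n",
              object@purity, nrow(object@segments), nrow(object@snvs)))
  invisible(NULL)
})

setMethod("show", "SignatureSummary", function(object) {
  cat("SignatureSummary:", object@sampleId, "\n")
  cat(sprintf("  TNSM %d (%.1f/Mb), FT %.3f, FA %.3f\n", object@tnsm,
              object@ratePerMb, object@ft, object@fa))
  invisible(NULL)
})
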