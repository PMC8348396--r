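#' Accessors for ECG containers
#'
#' @param object an [ECGSignal-class] or [BeatSet-class].
#' @return \code{fs}: sampling rate (Hz); \code{samples}: millivolt
#'   vector; \code{duration}: signal length in seconds; \code{beats}:
#'   fiducial data.frame; \code{rPeaks}: 0-based R-peak indices;
#'   \code{nBeats}: beat count; \code{isFlagged}: logical.
#' @name ecg-accessors
NULL

#' @rdname ecg-accessors
#' @export
setGeneric("fs", function(object) standardGeneric("fs"))
#' @rdname ecg-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname ecg-accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname ecg-accessors
#' @export
setGeneric("beats", function(object) standardGeneric("beats"))
#' @rdname ecg-accessors
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
#' @rdname ecg-accessors
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))
#' @rdname ecg-accessors
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))

#' @rdname ecg-accessors
setMethod("fs", "ECGSignal", function(object) object@fs)
#' @rdname ecg-accessors
setMethod("samples", "ECGSignal", function(object) object@samples)
#' @rdname ecg-accessors
setMethod("duration", "ECGSignal",
          function(object) length(object@samples) / object@fs)
#' @rdname ecg-accessors
setMethod("fs", "BeatSet", function(object) object@fs)
#' @rdname ecg-accessors
setMethod("beats", "BeatSet", function(object) object@beats)
#' @rdname ecg-accessors
setMethod("rPeaks", "BeatSet", function(object) object@beats$r_idx)
#' @rdname ecg-accessors
setMethod("nBeats", "BeatSet", function(object) nrow(object@beats))
#' @rdname ecg-accessors
setMethod("isFlagged", "BeatSet", function(object) object@flagged)

setMethod("show", "ECGSignal", function(object) {
  cat(sprintf("ECGSignal: %d samples @ %g Hz (%.1f s), lead %s, source %s\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              object@leadId, object@source))
})

setMethod("show", "RhythmSpec", function(object) {
  cat(sprintf("RhythmSpec: %s, mean RR %.3f s (jitter %.3f s), seed %d\n",
              object@rhythm, object@meanRR, object@rrJitter, object@seed))
  if (object@rhythm == "AF")
    cat(sprintf("  f waves: %.0f cycles/min, %.2f mV\n",
                object@fWaveRate, object@fWaveAmp))
  else
    cat(sprintf("  P: %.2f mV, PR %.3f s", object@pAmp, object@prInterval),
        if (object@rhythm == "PAF")
          sprintf(", premature prob %.2f\n", object@prematureProb)
        else "\n", sep = "")
})

setMethod("show", "BeatSet", function(object) {
  cat(sprintf("BeatSet: %d beats @ %g Hz over %d samples%s\n",
              nrow(object@beats), object@fs, as.integer(object@nSamples),
              if (object@flagged) " [flagged: unusable]" else ""))
  if (nrow(object@beats))
    cat(sprintf("  P waves present on %d/%d beats\n",
                sum(!object@beats$p_absent), nrow(object@beats)))
})

setMethod("show", "SVMFit", function(object) {
  cat(sprintf(
    "SVMFit: %s vs %s, %d support vectors, C = %g, gamma = %g\n",
    object@classes[1], object@classes[2], nrow(object@supportVectors),
    object@cost, object@gamma))
})

setMethod("show", "HybridModel", function(object) {
  cat("HybridModel (waterfall ensemble)\n  stage 1 (diagnosis):  ")
  show(object@diagnosis)
  cat("  stage 2 (prediction): ")
  show(object@prediction)
})

setMethod("show", "ReportImage", function(object) {
  d <- dim(object@pixels)
  cal <- object@calibration
  cat(sprintf(
    "ReportImage: %d x %d px, %g px/mm, %g mm/s, %g mm/mV\n",
    d[1], d[2], cal$px_per_mm, cal$mm_per_s, cal$mm_per_mV))
})
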