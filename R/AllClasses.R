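#' @import methods
NULL

#' ECGSignal: a uniformly sampled single-lead voltage trace
#'
#' Container for a single-lead ECG: a numeric vector of millivolt samples
#' together with its sampling rate and provenance. All downstream
#' operations (filtering, QRS detection, feature extraction) consume and
#' produce this class.
#'
#' @slot samples numeric vector of voltages in millivolts.
#' @slot fs sampling rate in Hz.
#' @slot leadId lead label (free text, e.g. \code{"II"}).
#' @slot source one of \code{"synthetic"}, \code{"wfdb"}, \code{"csv"},
#'   \code{"digitized"}.
#'
#' @seealso [ecgSignal()], [generateECG()], [readSignalCSV()]
#' @exportClass ECGSignal
setClass("ECGSignal",
  representation(samples = "numeric", fs = "numeric",
                 leadId = "character", source = "character"),
  prototype(samples = numeric(), fs = 250, leadId = "II",
            source = "synthetic"))

setValidity("ECGSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive finite number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one sample")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  if (!object@source %in% c("synthetic", "wfdb", "csv", "digitized"))
    msg <- c(msg, "'source' must be synthetic, wfdb, csv or digitized")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGSignal
#'
#' @param samples numeric millivolt samples.
#' @param fs sampling rate in Hz.
#' @param leadId lead label.
#' @param source provenance tag.
#' @return An [ECGSignal-class] object.
#' @examples
#' sig <- ecgSignal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' fs(sig)
#' @export
ecgSignal <- function(samples, fs, leadId = "II", source = "synthetic") {
  new("ECGSignal", samples = as.numeric(samples), fs = as.numeric(fs),
      leadId = leadId, source = source)
}

#' RhythmSpec: parameters of a synthetic cardiac rhythm
#'
#' Describes one of three rhythm regimes emulated by the generator:
#' \describe{
#'   \item{NSR}{normal sinus rhythm — regular RR around \code{meanRR},
#'     visible P waves.}
#'   \item{AF}{atrial fibrillation — irregular RR, P waves absent and
#'     replaced by fibrillatory (f) waves at \code{fWaveRate} cycles/min
#'     and amplitude \code{fWaveAmp} mV.}
#'   \item{PAF}{the sinus rhythm recorded before a paroxysmal-AF episode —
#'     sinus beats with occasional premature beats and perturbed P
#'     amplitude / PR interval.}
#' }
#'
#' Clinically, f waves run at 350–600 cycles/min with amplitudes of
#' roughly 0.05–0.50 mV; the constructor enforces these ranges for AF
#' specs unless \code{enforceRanges = FALSE}.
#'
#' @slot rhythm \code{"NSR"}, \code{"AF"} or \code{"PAF"}.
#' @slot meanRR mean RR interval, seconds.
#' @slot rrJitter standard deviation of RR perturbations, seconds.
#' @slot fWaveRate f-wave rate, cycles per minute (AF only; \code{NA} otherwise).
#' @slot fWaveAmp f-wave amplitude, mV (AF only; \code{NA} otherwise).
#' @slot pAmp P-wave amplitude, mV.
#' @slot prInterval P-onset to QRS-onset time, seconds.
#' @slot prematureProb per-beat probability of a premature beat (PAF only).
#' @slot noise list with elements \code{baseline_amp}, \code{baseline_freq},
#'   \code{powerline_amp}, \code{powerline_freq}, \code{white_sigma}.
#' @slot seed integer seed driving all randomness of the generator.
#'
#' @seealso [rhythmSpec()], [generateECG()]
#' @exportClass RhythmSpec
setClass("RhythmSpec",
  representation(rhythm = "character", meanRR = "numeric",
                 rrJitter = "numeric", fWaveRate = "numeric",
                 fWaveAmp = "numeric", pAmp = "numeric",
                 prInterval = "numeric", prematureProb = "numeric",
                 noise = "list", seed = "integer"))

setValidity("RhythmSpec", function(object) {
  msg <- character()
  if (!object@rhythm %in% c("NSR", "AF", "PAF"))
    msg <- c(msg, "'rhythm' must be NSR, AF or PAF")
  if (object@meanRR <= 0) msg <- c(msg, "'meanRR' must be positive")
  if (object@rrJitter < 0) msg <- c(msg, "'rrJitter' must be >= 0")
  if (object@prematureProb < 0 || object@prematureProb > 1)
    msg <- c(msg, "'prematureProb' must lie in [0, 1]")
  if (object@rhythm != "AF" &&
      (!is.na(object@fWaveRate) || !is.na(object@fWaveAmp)))
    msg <- c(msg, "f-wave fields are only valid for AF rhythm")
  need <- c("baseline_amp", "baseline_freq", "powerline_amp",
            "powerline_freq", "white_sigma")
  if (!all(need %in% names(object@noise)))
    msg <- c(msg, paste("'noise' must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' BeatSet: per-beat fiducial points
#'
#' One row per beat with 0-based sample indices of the R peak, QRS onset,
#' P peak and P onset (the P columns are \code{NA} where no P wave is
#' present or detected), plus the beat type. Used both for ground truth
#' emitted by the generator and for the output of [delineateBeats()].
#'
#' @slot beats data.frame with columns \code{r_idx}, \code{qrs_on_idx},
#'   \code{p_peak_idx}, \code{p_on_idx}, \code{p_absent} (logical),
#'   \code{beat_type} (\code{"normal"} or \code{"premature"}).
#' @slot fs sampling rate the indices refer to, Hz.
#' @slot nSamples length of the underlying signal.
#' @slot flagged TRUE when detection found too few beats to be usable.
#'
#' @seealso [beatSet()], [detectRPeaks()], [delineateBeats()]
#' @exportClass BeatSet
setClass("BeatSet",
  representation(beats = "data.frame", fs = "numeric",
                 nSamples = "numeric", flagged = "logical"),
  prototype(flagged = FALSE))

setValidity("BeatSet", function(object) {
  msg <- character()
  need <- c("r_idx", "qrs_on_idx", "p_peak_idx", "p_on_idx",
            "p_absent", "beat_type")
  if (!all(need %in% names(object@beats)))
    msg <- c(msg, paste("'beats' must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    b <- object@beats
    if (nrow(b)) {
      if (any(b$r_idx < 0 | b$r_idx >= object@nSamples))
        msg <- c(msg, "r_idx out of signal range")
      if (is.unsorted(b$r_idx, strictly = TRUE))
        msg <- c(msg, "r_idx must be strictly increasing")
      ok <- !b$p_absent & !is.na(b$p_on_idx) & !is.na(b$p_peak_idx) &
        !is.na(b$qrs_on_idx)
      if (any(ok & !(b$p_on_idx < b$p_peak_idx &
                     b$p_peak_idx < b$qrs_on_idx &
                     b$qrs_on_idx <= b$r_idx)))
        msg <- c(msg, "fiducial ordering p_on < p_peak < qrs_on <= r violated")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BeatSet
#'
#' @param beats data.frame of fiducials (see [BeatSet-class]); missing
#'   columns are filled with \code{NA} / defaults.
#' @param fs sampling rate in Hz.
#' @param nSamples length of the underlying signal.
#' @param flagged TRUE to mark an unusable (too-few-beats) result.
#' @return A [BeatSet-class] object.
#' @export
beatSet <- function(beats, fs, nSamples, flagged = FALSE) {
  if (is.null(beats) || nrow(beats) == 0L)
    beats <- data.frame(r_idx = numeric(), qrs_on_idx = numeric(),
                        p_peak_idx = numeric(), p_on_idx = numeric(),
                        p_absent = logical(), beat_type = character())
  for (col in c("qrs_on_idx", "p_peak_idx", "p_on_idx"))
    if (is.null(beats[[col]])) beats[[col]] <- rep(NA_real_, nrow(beats))
  if (is.null(beats$p_absent)) beats$p_absent <- is.na(beats$p_peak_idx)
  if (is.null(beats$beat_type)) beats$beat_type <- rep("normal", nrow(beats))
  new("BeatSet", beats = beats, fs = as.numeric(fs),
      nSamples = as.numeric(nSamples), flagged = flagged)
}

#' SVMFit: a fitted RBF support vector machine
#'
#' Stores everything needed to evaluate the kernel decision function
#' \deqn{f(x) = \mathrm{sign}\Big(\sum_i \alpha_i^* y_i
#'   \exp(-\gamma \|x_i - x\|^2) + b^*\Big)}
#' explicitly: the support vectors \eqn{x_i} (already on the scaled
#' feature scale), the products \eqn{\alpha_i^* y_i}, the bias
#' \eqn{b^*}, the kernel width \eqn{\gamma}, the regularization constant
#' C, and the feature scaler frozen on the training set.
#'
#' @slot supportVectors numeric matrix, one scaled support vector per row.
#' @slot dualCoefs numeric vector of \eqn{\alpha_i^* y_i}.
#' @slot bias intercept \eqn{b^*}.
#' @slot gamma RBF kernel width.
#' @slot cost regularization constant C.
#' @slot scaler list with \code{center}, \code{spread}, \code{features}
#'   (see [fitScaler()]).
#' @slot classes length-2 character; the first class maps to +1.
#' @slot features feature column names in training order.
#'
#' @seealso [svmTrain()], [svmDecide()]
#' @exportClass SVMFit
setClass("SVMFit",
  representation(supportVectors = "matrix", dualCoefs = "numeric",
                 bias = "numeric", gamma = "numeric", cost = "numeric",
                 scaler = "list", classes = "character",
                 features = "character"))

setValidity("SVMFit", function(object) {
  msg <- character()
  if (nrow(object@supportVectors) != length(object@dualCoefs))
    msg <- c(msg, "one dual coefficient per support vector required")
  if (length(object@classes) != 2L)
    msg <- c(msg, "'classes' must name exactly two classes")
  if (length(object@cost) == 1L && is.finite(object@cost) &&
      any(abs(object@dualCoefs) > object@cost + 1e-8))
    msg <- c(msg, "|dual coefficients| must not exceed C")
  if (length(msg)) msg else TRUE
})

#' HybridModel: the two-stage waterfall ensemble
#'
#' Stage 1 (diagnosis) separates AF from non-AF segments using the six
#' RR-interval features; stage 2 (prediction) runs only on segments
#' stage 1 calls N and separates PAF-precursor from normal segments
#' using all 14 features. Each stage carries its own frozen scaler.
#'
#' @slot diagnosis [SVMFit-class] with classes \code{c("AF", "N")}.
#' @slot prediction [SVMFit-class] with classes \code{c("PAF", "N")}.
#' @slot imputeMeans named numeric; training means used to impute
#'   missing P-wave features at stage 2.
#'
#' @seealso [trainHybrid()], [predictHybrid()]
#' @exportClass HybridModel
setClass("HybridModel",
  representation(diagnosis = "SVMFit", prediction = "SVMFit",
                 imputeMeans = "numeric"))

setValidity("HybridModel", function(object) {
  msg <- character()
  if (!identical(sort(object@diagnosis@classes), c("AF", "N")))
    msg <- c(msg, "diagnosis stage must use classes {AF, N}")
  if (!identical(sort(object@prediction@classes), c("N", "PAF")))
    msg <- c(msg, "prediction stage must use classes {PAF, N}")
  if (length(msg)) msg else TRUE
})

#' ReportImage: a rasterized ECG report strip
#'
#' A 3-channel image of an ECG trace over a standard 1 mm / 5 mm
#' calibration grid, together with the affine calibration that maps
#' pixels to seconds and millivolts (so digitization can be scored
#' against the source signal).
#'
#' @slot pixels numeric array \code{height x width x 3} with values in
#'   \code{[0, 1]} (as read/written by the png package).
#' @slot calibration list: \code{px_per_mm}, \code{mm_per_s},
#'   \code{mm_per_mV}, \code{baseline_row} (1-based pixel row of 0 mV),
#'   \code{x0} (1-based pixel column of time 0), \code{fs} of the source.
#'
#' @seealso [renderReport()], [digitizeReport()]
#' @exportClass ReportImage
setClass("ReportImage",
  representation(pixels = "array", calibration = "list"))

setValidity("ReportImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'pixels' must be a height x width x 3 array")
  if (any(object@pixels < 0 | object@pixels > 1))
    msg <- c(msg, "pixel values must lie in [0, 1]")
  need <- c("px_per_mm", "mm_per_s", "mm_per_mV", "baseline_row", "x0")
  if (!all(need %in% names(object@calibration)))
    msg <- c(msg, paste("'calibration' must contain:",
                        paste(need, collapse = ", ")))
  else if (any(unlist(object@calibration[c("px_per_mm", "mm_per_s",
                                           "mm_per_mV")]) <= 0))
    msg <- c(msg, "calibration scales must be positive")
  if (length(msg)) msg else TRUE
})
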