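#' Time-domain RR-interval features
#'
#' The six RR statistics used by the diagnosis stage: mean, sample
#' (n-1) standard deviation, maximum, root-mean-square of the RR series,
#' range (max - min) and count. The irregularity of the ventricular
#' response during AF makes \code{rr_std} and \code{rr_cha} the primary
#' discriminators.
#'
#' @param rr numeric vector of RR intervals in seconds (all positive,
#'   at least two).
#' @param rms \code{"rms"} (default) takes the literal root mean
#'   square of the RR series; \code{"rmssd"} substitutes the HRV
#'   convention, the root mean square of successive RR differences.
#' @return Named numeric vector with \code{rr_std}, \code{rr_mean},
#'   \code{rr_max}, \code{rr_rms}, \code{rr_cha}, \code{rr_len}.
#' @examples
#' rrFeatures(c(0.6, 1.0))
#' @export
rrFeatures <- function(rr, rms = c("rms", "rmssd")) {
  rms <- match.arg(rms)
  stopIfNot(length(rr) >= 2, "at least two RR intervals required")
  stopIfNot(all(rr > 0), "RR intervals must be positive")
  rrRms <- if (rms == "rms") sqrt(mean(rr^2))
           else sqrt(mean(diff(rr)^2))
  c(rr_std = stats::sd(rr), rr_mean = mean(rr), rr_max = max(rr),
    rr_rms = rrRms, rr_cha = max(rr) - min(rr),
    rr_len = length(rr))
}

#' PR interval of one delineated beat
#'
#' The absolute distance between the QRS onset and the P onset,
#' \eqn{PR = |QRS_{on} - P_{on}|}, in seconds. A peak-to-peak variant
#' (P peak to R peak) is available via \code{from = "peak"} for
#' workflows that anchor the interval on wave apices instead of
#' onsets.
#'
#' @param beat one row of a [BeatSet-class] \code{beats} data.frame (or
#'   any list with \code{qrs_on_idx} and \code{p_on_idx}; \code{r_idx}
#'   and \code{p_peak_idx} for the peak variant).
#' @param fs sampling rate in Hz.
#' @param from anchor the interval on wave \code{"onset"}s (default)
#'   or \code{"peak"}s.
#' @return PR interval in seconds, or \code{NA} for a P-absent beat.
#' @export
prInterval <- function(beat, fs, from = c("onset", "peak")) {
  from <- match.arg(from)
  a <- if (from == "onset") beat$qrs_on_idx else beat$r_idx
  b <- if (from == "onset") beat$p_on_idx else beat$p_peak_idx
  if (is.na(a) || is.na(b)) return(NA_real_)
  abs(a - b) / fs
}

#' P-wave amplitude of one delineated beat
#'
#' Amplitude at the P peak minus amplitude at the P onset,
#' \eqn{amp_P - amp_{Pon}}, read from the signal samples.
#'
#' @param sig an [ECGSignal-class].
#' @param beat one row of a [BeatSet-class] \code{beats} data.frame.
#' @return amplitude in mV, or \code{NA} for a P-absent beat.
#' @export
pAmplitude <- function(sig, beat) {
  if (is.na(beat$p_peak_idx) || is.na(beat$p_on_idx)) return(NA_real_)
  x <- samples(sig)
  x[beat$p_peak_idx + 1] - x[beat$p_on_idx + 1]
}

#' Frequency-domain wavelet features of the P band
#'
#' Concatenates the per-beat P search windows (\code{[QRS_on - 240 ms,
#' QRS_on - 40 ms]} around each beat; the whole signal when
#' \code{pBand = "whole"}), decomposes the resulting P-band signal with
#' a multi-level bior5.5 transform, and summarizes the level-4
#' approximation vector by (mean, standard deviation, energy) ->
#' \code{(ca1, ca2, ca3)} and the level-4 detail vector likewise ->
#' \code{(cd1, cd2, cd3)}. A P band shorter than the level-4 support is
#' zero-padded with a warning.
#'
#' @param sig an [ECGSignal-class].
#' @param bs a [BeatSet-class] (detected or ground truth).
#' @param levels decomposition depth (the level-4 vectors are
#'   summarized, so at least 4).
#' @param pBand \code{"perbeat"} (default) or \code{"whole"}.
#' @return Named numeric vector \code{ca1..ca3, cd1..cd3}.
#' @export
waveletFeatures <- function(sig, bs, levels = 5, pBand = c("perbeat", "whole")) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  pBand <- match.arg(pBand)
  stopIfNot(levels >= 4, "'levels' must be at least 4")
  f <- fs(sig)
  x <- samples(sig)
  if (pBand == "whole") {
    band <- x
  } else {
    stopIfNot(is(bs, "BeatSet"), "'bs' must be a BeatSet")
    b <- beats(bs)
    w240 <- round(0.240 * f); w40 <- round(0.040 * f)
    anchor <- ifelse(is.na(b$qrs_on_idx),
                     b$r_idx - round(0.05 * f), b$qrs_on_idx)
    segs <- lapply(anchor, function(a) {
      lo <- a - w240 + 1; hi <- a - w40 + 1       # 1-based
      if (lo < 1 || hi > length(x) || hi <= lo) return(NULL)
      x[lo:hi]
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    stopIfNot(length(segs) >= 1, "no in-range P windows available")
    band <- unlist(segs)
  }
  minLen <- 2^4
  if (length(band) < minLen) {
    warning("P band shorter than the level-4 support; zero-padding")
    band <- c(band, numeric(minLen - length(band)))
  }
  dec <- waveDecBior55(band, levels)
  cA4 <- dec$cA[[4]]; cD4 <- dec$cD[[4]]
  c(ca1 = mean(cA4), ca2 = stats::sd(cA4), ca3 = sum(cA4^2),
    cd1 = mean(cD4), cd2 = stats::sd(cD4), cd3 = sum(cD4^2))
}

#' The 14 feature columns of a segment feature table
#'
#' @return Character vectors: all 14 features, the 6 RR features used
#'   by the diagnosis stage, and the 8 P/wavelet features specific to
#'   the prediction stage.
#' @export
featureColumns <- function() {
  list(all = c("rr_std", "rr_mean", "rr_max", "rr_rms", "rr_cha",
               "rr_len", "pr", "pamp", "ca1", "ca2", "ca3",
               "cd1", "cd2", "cd3"),
       diagnosis = c("rr_std", "rr_mean", "rr_max", "rr_rms", "rr_cha",
                     "rr_len"),
       prediction = c("rr_std", "rr_mean", "rr_max", "rr_rms", "rr_cha",
                      "rr_len", "pr", "pamp", "ca1", "ca2", "ca3",
                      "cd1", "cd2", "cd3"))
}

#' Extract the full 14-feature vector of one ECG segment
#'
#' Runs detection and delineation (unless a [BeatSet-class] is
#' supplied), then assembles the six RR features, the mean PR interval
#' and mean P amplitude over beats with a detected P wave, and the six
#' level-4 bior5.5 wavelet summaries of the P band. P-dependent
#' features are \code{NA} when every beat is P-absent (as in AF).
#'
#' @param sig an [ECGSignal-class] segment.
#' @param bs optional [BeatSet-class]; computed via [detectRPeaks()] +
#'   [delineateBeats()] when missing.
#' @param label segment label (\code{"N"}, \code{"AF"}, \code{"PAF"} or
#'   \code{NA}).
#' @param ... passed to [delineateBeats()].
#' @return A one-row data.frame with the 14 features plus \code{label}.
#' @examples
#' seg <- generateECG(nsrSpec(seed = 2), 60, 250)
#' segmentFeatures(seg$signal, label = "N")
#' @export
segmentFeatures <- function(sig, bs = NULL, label = NA_character_, ...) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  if (is.null(bs)) {
    det <- detectRPeaks(sig)
    if (isFlagged(det))
      stop("too few beats detected; segment unusable", call. = FALSE)
    bs <- delineateBeats(sig, rPeaks(det), ...)
  }
  b <- beats(bs)
  stopIfNot(nrow(b) >= 3, "at least three beats required per segment")
  rr <- diff(b$r_idx) / fs(bs)
  feat <- as.list(rrFeatures(rr))
  usable <- which(!b$p_absent)
  if (length(usable)) {
    prs <- vapply(usable, function(i) prInterval(b[i, ], fs(bs)), numeric(1))
    amps <- if (!is.null(b$p_amp_mv)) b$p_amp_mv[usable]
            else vapply(usable, function(i) pAmplitude(sig, b[i, ]), numeric(1))
    feat$pr <- mean(prs, na.rm = TRUE)
    feat$pamp <- mean(amps, na.rm = TRUE)
    wf <- waveletFeatures(sig, bs)
    feat <- c(feat, as.list(wf))
  } else {
    feat <- c(feat, stats::setNames(
      as.list(rep(NA_real_, 8)),
      c("pr", "pamp", "ca1", "ca2", "ca3", "cd1", "cd2", "cd3")))
  }
  out <- as.data.frame(feat)[, featureColumns()$all]
  out$label <- label
  out
}

#' Fit / apply / invert a z-score feature scaler
#'
#' \code{fitScaler} learns per-feature center (mean) and spread
#' (population standard deviation, divisor n, so two training values
#' \code{c(1, 3)} scale exactly to \code{c(-1, +1)}) on training rows;
#' a zero spread is clamped to 1 with a warning so constant features
#' scale to zero.
#' \code{applyScaler} uses the frozen training parameters only;
#' \code{invertScaler} maps scaled values back.
#'
#' @param x data.frame or matrix of training feature rows.
#' @param scaler a fitted scaler.
#' @param features columns to scale (default: all numeric columns of
#'   \code{x} at fit time; the scaler's own columns afterwards).
#' @return \code{fitScaler}: list with \code{center}, \code{spread},
#'   \code{features}; \code{applyScaler}/\code{invertScaler}: object
#'   like \code{x} with the scaler's columns transformed.
#' @examples
#' sc <- fitScaler(data.frame(a = c(1, 3)))
#' applyScaler(sc, data.frame(a = c(1, 3)))$a   # -1, +1
#' @export
fitScaler <- function(x, features = NULL) {
  x <- as.data.frame(x)
  stopIfNot(nrow(x) >= 1, "training set must be nonempty")
  if (is.null(features))
    features <- names(x)[vapply(x, is.numeric, logical(1))]
  center <- vapply(features, function(f) mean(x[[f]], na.rm = TRUE),
                   numeric(1))
  spread <- vapply(features, function(f) {
    v <- x[[f]][!is.na(x[[f]])]
    if (!length(v)) NA_real_ else sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  spread[is.na(spread)] <- 0
  if (any(spread == 0)) {
    warning("zero-spread feature(s) clamped to unit spread: ",
            paste(features[spread == 0], collapse = ", "))
    spread[spread == 0] <- 1
  }
  list(center = center, spread = spread, features = features)
}

#' @rdname fitScaler
#' @export
applyScaler <- function(scaler, x) {
  x <- as.data.frame(x)
  for (f in scaler$features)
    x[[f]] <- (x[[f]] - scaler$center[[f]]) / scaler$spread[[f]]
  x
}

#' @rdname fitScaler
#' @export
invertScaler <- function(scaler, x) {
  x <- as.data.frame(x)
  for (f in scaler$features)
    x[[f]] <- x[[f]] * scaler$spread[[f]] + scaler$center[[f]]
  x
}
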