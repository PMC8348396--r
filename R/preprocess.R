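#' Filter bank for the QRS-emphasis transformation chain
#'
#' The classic chain: a 5–15 Hz zero-phase bandpass to emphasize the QRS
#' complex while suppressing T waves, baseline drift, EMG and mains
#' interference; a five-point derivative; elementwise squaring; and a
#' 150 ms moving-window integrator.
#'
#' @param lowpassCutoff upper passband edge, Hz.
#' @param highpassCutoff lower passband edge, Hz.
#' @param derivativeKernel convolution kernel of the slope amplifier.
#' @param mwiWindow moving-window-integrator length, seconds.
#' @return A list of class \code{"FilterBank"}.
#' @export
filterBank <- function(lowpassCutoff = 15, highpassCutoff = 5,
                       derivativeKernel = c(-1, -2, 0, 2, 1) / 8,
                       mwiWindow = 0.150) {
  stopIfNot(highpassCutoff > 0 && lowpassCutoff > highpassCutoff,
            "need 0 < highpassCutoff < lowpassCutoff")
  stopIfNot(mwiWindow > 0, "'mwiWindow' must be positive")
  structure(list(lowpass_cutoff = lowpassCutoff,
                 highpass_cutoff = highpassCutoff,
                 derivative_kernel = derivativeKernel,
                 mwi_window = mwiWindow),
            class = "FilterBank")
}

#' Zero-phase bandpass filter
#'
#' Applies a Butterworth bandpass forward and backward
#' (\code{signal::filtfilt}), giving zero phase shift and unit passband
#' gain at the band centre.
#'
#' @param sig an [ECGSignal-class].
#' @param fb a [filterBank()]; its cutoffs define the passband.
#' @param order Butterworth order (per direction).
#' @return A filtered [ECGSignal-class] of the same length.
#' @export
bandpassECG <- function(sig, fb = filterBank(), order = 2) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  nyq <- fs(sig) / 2
  if (fb$lowpass_cutoff >= nyq)
    stop(sprintf("lowpass cutoff %g Hz is at or above Nyquist (%g Hz)",
                 fb$lowpass_cutoff, nyq), call. = FALSE)
  bf <- signal::butter(order,
                       c(fb$highpass_cutoff, fb$lowpass_cutoff) / nyq,
                       type = "pass")
  y <- signal::filtfilt(bf, samples(sig))
  ecgSignal(y, fs(sig), sig@leadId, sig@source)
}

# Zero-phase lowpass, used by the delineator's P-search path.
lowpassECG <- function(sig, cutoff, order = 4) {
  nyq <- fs(sig) / 2
  stopIfNot(cutoff < nyq, "cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  ecgSignal(signal::filtfilt(bf, samples(sig)), fs(sig),
            sig@leadId, sig@source)
}

#' Derivative, squaring and moving-window integration
#'
#' \code{derivativeECG} convolves with the five-point slope kernel
#' (edges zero-filled); \code{squareECG} squares elementwise;
#' \code{mwiECG} applies the causal moving mean over
#' \code{round(window * fs)} samples (a unit impulse becomes N samples
#' of value 1/N).
#'
#' @param sig an [ECGSignal-class].
#' @param fb a [filterBank()] supplying the derivative kernel.
#' @param window integrator length in seconds (\code{window * fs >= 1}).
#' @return An [ECGSignal-class] of the same length.
#' @name transform-chain
NULL

#' @rdname transform-chain
#' @export
derivativeECG <- function(sig, fb = filterBank()) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  k <- rev(fb$derivative_kernel)      # convolution
  y <- stats::filter(samples(sig), k, method = "convolution", sides = 2)
  y[is.na(y)] <- 0
  ecgSignal(as.numeric(y), fs(sig), sig@leadId, sig@source)
}

#' @rdname transform-chain
#' @export
squareECG <- function(sig) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  ecgSignal(samples(sig)^2, fs(sig), sig@leadId, sig@source)
}

#' @rdname transform-chain
#' @export
mwiECG <- function(sig, window = 0.150) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  n <- round(window * fs(sig))
  stopIfNot(n >= 1, "'window' must span at least one sample")
  x <- samples(sig)
  cs <- cumsum(x)
  y <- (cs - c(rep(0, n), cs[seq_len(max(0, length(x) - n))])) / n
  ecgSignal(y, fs(sig), sig@leadId, sig@source)
}

#' Detect R peaks with adaptive dynamic thresholds
#'
#' Runs the transformation chain (bandpass, derivative, square,
#' moving-window integration), then locates QRS complexes on the
#' integrated signal with adaptive signal/noise thresholds: an accepted
#' peak updates the signal level as
#' \code{0.125 * peak + 0.875 * level} (rejected peaks update the noise
#' level analogously), the decision threshold is
#' \code{noise + 0.25 * (signal - noise)}, peaks closer than the
#' refractory period keep only the larger, and any inter-peak gap longer
#' than \code{searchbackFactor} times the running mean of the last eight
#' RR intervals is re-scanned at half the threshold (search-back).
#' Accepted integrator peaks are finally mapped to the nearest local
#' maximum of the bandpassed signal.
#'
#' @param sig an [ECGSignal-class].
#' @param fb a [filterBank()].
#' @param refractory minimum inter-beat spacing, seconds.
#' @param searchbackFactor gap multiple that triggers search-back.
#' @return A [BeatSet-class] of R-peak fiducials (0-based indices);
#'   flagged when fewer than two peaks are found.
#' @examples
#' out <- generateECG(nsrSpec(seed = 3), 30, 250)
#' det <- detectRPeaks(out$signal)
#' nBeats(det)
#' @export
detectRPeaks <- function(sig, fb = filterBank(), refractory = 0.200,
                         searchbackFactor = 1.66) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  stopIfNot(searchbackFactor > 1, "'searchbackFactor' must exceed 1")
  f <- fs(sig)
  bp <- samples(bandpassECG(sig, fb))
  mw <- samples(mwiECG(squareECG(derivativeECG(
    ecgSignal(bp, f, sig@leadId, sig@source), fb)), fb$mwi_window))
  n <- length(mw)
  refN <- round(refractory * f)

  ## candidate fiducials: local maxima of the integrated signal
  isPk <- which(diff(sign(diff(mw))) < 0) + 1L
  isPk <- isPk[mw[isPk] > 0]
  if (!length(isPk))
    return(beatSet(NULL, f, n, flagged = TRUE))

  initWin <- seq_len(min(n, round(2.5 * f)))
  spk <- 0.5 * max(mw[initWin])
  npk <- 0.5 * mean(mw[initWin])
  accepted <- integer(0)
  rrBuf <- numeric(0)

  acceptPeak <- function(i, accepted, rrBuf) {
    if (length(accepted))
      rrBuf <<- c(utils::tail(rrBuf, 7), (i - accepted[length(accepted)]) / f)
    c(accepted, i)
  }

  for (i in isPk) {
    thr <- npk + 0.25 * (spk - npk)
    last <- if (length(accepted)) accepted[length(accepted)] else -Inf
    if (i - last < refN) {
      # refractory violation: keep the larger of the two
      if (mw[i] > mw[last]) {
        accepted[length(accepted)] <- i
        spk <- 0.125 * mw[i] + 0.875 * spk
      }
      next
    }
    if (mw[i] > thr) {
      # search-back first: did we miss a beat inside a long gap?
      if (length(rrBuf) >= 2) {
        rrMean <- mean(rrBuf)
        if ((i - last) / f > searchbackFactor * rrMean) {
          gap <- isPk[isPk > last + refN & isPk < i - refN]
          gap <- gap[mw[gap] > 0.5 * thr]
          if (length(gap)) {
            sb <- gap[which.max(mw[gap])]
            accepted <- acceptPeak(sb, accepted, rrBuf)
            spk <- 0.125 * mw[sb] + 0.875 * spk
          }
        }
      }
      accepted <- acceptPeak(i, accepted, rrBuf)
      spk <- 0.125 * mw[i] + 0.875 * spk
    } else {
      npk <- 0.125 * mw[i] + 0.875 * npk
    }
  }
  if (length(accepted) < 2L)
    return(beatSet(NULL, f, n, flagged = TRUE))

  ## map integrator fiducials back to R peaks on the bandpassed signal:
  ## the integrator output lags the QRS by up to the MWI window
  lagN <- as.integer(round(fb$mwi_window * f))
  rIdx <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i - lagN - round(0.04 * f)))
    hi <- min(n, as.integer(i + round(0.04 * f)))
    j <- lo - 1L + which.max(bp[lo:hi])
    # refine to the nearest local maximum of bp
    repeat {
      if (j > 1L && bp[j - 1L] > bp[j]) j <- j - 1L
      else if (j < n && bp[j + 1L] > bp[j]) j <- j + 1L
      else break
    }
    j
  }, integer(1))
  rIdx <- sort(unique(rIdx))
  ## final refractory pass on mapped peaks: drop the lower of two
  keep <- rep(TRUE, length(rIdx))
  i <- 2L
  while (i <= length(rIdx)) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (rIdx[i] - rIdx[prev] < refN) {
      if (bp[rIdx[i]] >= bp[rIdx[prev]]) keep[prev] <- FALSE
      else keep[i] <- FALSE
    }
    i <- i + 1L
  }
  rIdx <- rIdx[keep]
  if (length(rIdx) < 2L)
    return(beatSet(NULL, f, n, flagged = TRUE))
  beatSet(data.frame(r_idx = rIdx - 1L), f, n)   # 0-based convention
}

#' Delineate QRS onset and P waves around detected R peaks
#'
#' Per beat: the QRS onset is the last sample before the R upstroke
#' where the slope of the cleaned signal falls below 10\% of the beat's
#' maximum upstroke slope. For the P search, the QRS complexes are
#' first blanked (linearly bridged) and the result low-passed (default
#' 4.5 Hz cutoff), which suppresses fibrillatory waves while retaining
#' the P hump and keeps the QRS from leaking into the search window.
#' The window is \code{[QRS_on - 240 ms, QRS_on - 40 ms]}, with its
#' left edge additionally kept at least \code{tRefractory} after the
#' previous R peak so the previous beat's T wave stays outside. The P
#' peak is the window argmax; the beat is marked P-absent when the
#' peak's prominence over the window's leading baseline falls below
#' \code{pProminence}, when the argmax sits on a window edge, or when
#' the window's fibrillatory ripple — the standard deviation of the
#' above-\code{pLowpass} residual, which is large exactly when f waves
#' replace the P wave — exceeds \code{fRippleMax}. The P onset is the
#' last pre-peak sample whose amplitude has dropped back to within
#' 10\% of the prominence of the leading baseline.
#'
#' @param sig an [ECGSignal-class] (raw).
#' @param rIdx 0-based R-peak indices (e.g. \code{rPeaks(detectRPeaks(sig))}).
#' @param pProminence minimum P prominence in mV on the low-passed
#'   signal.
#' @param pLowpass cutoff of the P-search lowpass, Hz.
#' @param tRefractory minimum distance of the window's left edge from
#'   the previous R peak, seconds (T-wave exclusion).
#' @param fRippleMax maximum tolerated f-wave ripple (mV, standard
#'   deviation of the high-band residual in the window) for a P call.
#' @return A [BeatSet-class] with QRS-onset and P fiducials; the first
#'   beat is skipped for P features when its search window precedes the
#'   record start.
#' @export
delineateBeats <- function(sig, rIdx, pProminence = 0.025, pLowpass = 4.5,
                           tRefractory = 0.35, fRippleMax = 0.06) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  f <- fs(sig)
  n <- length(samples(sig))
  rIdx <- sort(as.integer(rIdx))
  stopIfNot(all(rIdx >= 0 & rIdx < n), "R indices out of signal range")
  clean <- samples(lowpassECG(sig, cutoff = min(40, f / 2 - 1), order = 2))
  slope <- c(0, diff(clean)) * f
  ## blank the QRS complexes before smoothing so the R wave cannot
  ## leak a skirt into the P search windows
  blanked <- samples(sig)
  for (r0 in rIdx) {
    lo <- max(1L, r0 + 1L - round(0.06 * f))
    hi <- min(n, r0 + 1L + round(0.10 * f))
    blanked[lo:hi] <- seq(blanked[lo], blanked[hi],
                          length.out = hi - lo + 1L)
  }
  pSig <- samples(lowpassECG(ecgSignal(blanked, f), cutoff = pLowpass,
                             order = 4))

  nb <- length(rIdx)
  out <- data.frame(r_idx = rIdx,
                    qrs_on_idx = rep(NA_real_, nb),
                    p_peak_idx = rep(NA_real_, nb),
                    p_on_idx = rep(NA_real_, nb),
                    p_absent = rep(TRUE, nb),
                    beat_type = rep("normal", nb),
                    p_amp_mv = rep(NA_real_, nb))
  w240 <- round(0.240 * f); w40 <- round(0.040 * f)
  for (b in seq_len(nb)) {
    r1 <- rIdx[b] + 1L                       # 1-based
    ## QRS onset from the upstroke slope
    lo <- max(1L, r1 - round(0.10 * f))
    if (lo < r1) {
      seg <- lo:r1
      jmax <- seg[which.max(slope[seg])]
      smax <- slope[jmax]
      qOn <- lo
      if (smax > 0) {
        below <- seg[seg <= jmax & abs(slope[seg]) < 0.1 * smax]
        if (length(below)) qOn <- max(below)
      }
      out$qrs_on_idx[b] <- qOn - 1L
    } else next
    ## P search window, left edge kept clear of the previous T wave
    pLo <- (qOn - 1L) - w240 + 1L
    if (b > 1L)
      pLo <- max(pLo, rIdx[b - 1L] + 1L + round(tRefractory * f))
    pHi <- (qOn - 1L) - w40 + 1L
    if (pLo < 1L || pHi - pLo < round(0.04 * f)) next  # window unusable
    win <- pLo:pHi
    w <- pSig[win]
    baseline <- stats::median(w[seq_len(max(1L, round(0.040 * f)))])
    d <- w - baseline
    pkRel <- which.max(d)
    prom <- d[pkRel]
    if (is.na(prom) || prom < pProminence) next
    if (pkRel == 1L || pkRel == length(w)) next  # edge argmax: no hump
    ## fibrillatory-ripple veto: strong high-band oscillation in the
    ## window means f waves, not a P wave
    if (stats::sd(clean[win] - pSig[win]) > fRippleMax) next
    pk <- win[pkRel]
    ## P onset: last sample before the peak where the amplitude has
    ## dropped back to within 10% of the prominence of the baseline
    eps <- 0.1 * prom
    pre <- which(d[seq_len(pkRel - 1L)] <= eps)
    pOn <- if (length(pre)) win[max(pre)] else pLo
    out$p_peak_idx[b] <- pk - 1L
    out$p_on_idx[b] <- pOn - 1L
    out$p_absent[b] <- FALSE
    out$p_amp_mv[b] <- clean[pk] - clean[pOn]
  }
  beatSet(out, f, n)
}
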