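#' Noise specification for the ECG generator
#'
#' @param baseline_amp amplitude of sinusoidal baseline wander, mV.
#' @param baseline_freq baseline wander frequency, Hz (respiratory range).
#' @param powerline_amp amplitude of mains interference, mV.
#' @param powerline_freq mains frequency, Hz (50 or 60).
#' @param white_sigma standard deviation of additive broadband noise, mV.
#' @return A named list usable as the \code{noise} slot of a
#'   [RhythmSpec-class].
#' @export
noiseSpec <- function(baseline_amp = 0, baseline_freq = 0.3,
                      powerline_amp = 0, powerline_freq = 50,
                      white_sigma = 0) {
  list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
       powerline_amp = powerline_amp, powerline_freq = powerline_freq,
       white_sigma = white_sigma)
}

#' Construct a rhythm specification
#'
#' Builds a validated [RhythmSpec-class]. For AF, the f-wave rate and
#' amplitude must fall in the clinically reported ranges 350–600
#' cycles/min and 0.05–0.50 mV unless \code{enforceRanges = FALSE}.
#'
#' @param rhythm \code{"NSR"}, \code{"AF"} or \code{"PAF"}
#'   (PAF = sinus rhythm preceding a paroxysmal-AF episode).
#' @param meanRR mean RR interval, seconds.
#' @param rrJitter standard deviation of RR perturbations, seconds.
#' @param fWaveRate f-wave rate in cycles/min (AF only).
#' @param fWaveAmp f-wave amplitude in mV (AF only).
#' @param pAmp P-wave amplitude, mV.
#' @param prInterval P-onset to QRS-onset interval, seconds.
#' @param prematureProb per-beat probability of a premature beat.
#' @param noise see [noiseSpec()].
#' @param seed integer seed; the generator is deterministic given it.
#' @param enforceRanges enforce the AF f-wave ranges above.
#' @return A [RhythmSpec-class] object.
#' @examples
#' nsrSpec(seed = 7)
#' afSpec(fWaveRate = 420, seed = 7)
#' @export
rhythmSpec <- function(rhythm, meanRR, rrJitter, fWaveRate = NA_real_,
                       fWaveAmp = NA_real_, pAmp = 0.2, prInterval = 0.16,
                       prematureProb = 0, noise = noiseSpec(), seed = 1L,
                       enforceRanges = TRUE) {
  if (rhythm == "AF" && enforceRanges) {
    if (is.na(fWaveRate) || fWaveRate < 350 || fWaveRate > 600)
      stop("AF f-wave rate must lie in 350-600 cycles/min ",
           "(override with enforceRanges = FALSE)", call. = FALSE)
    if (is.na(fWaveAmp) || fWaveAmp < 0.05 || fWaveAmp > 0.50)
      stop("AF f-wave amplitude must lie in 0.05-0.50 mV ",
           "(override with enforceRanges = FALSE)", call. = FALSE)
  }
  new("RhythmSpec", rhythm = rhythm, meanRR = meanRR, rrJitter = rrJitter,
      fWaveRate = as.numeric(fWaveRate), fWaveAmp = as.numeric(fWaveAmp),
      pAmp = pAmp, prInterval = prInterval, prematureProb = prematureProb,
      noise = noise, seed = as.integer(seed))
}

#' @rdname rhythmSpec
#' @param ... overrides passed on to [rhythmSpec()].
#' @export
nsrSpec <- function(..., seed = 1L) {
  args <- utils::modifyList(
    list(rhythm = "NSR", meanRR = 0.8, rrJitter = 0.03, pAmp = 0.2,
         prInterval = 0.16, seed = seed), list(...))
  do.call(rhythmSpec, args)
}

#' @rdname rhythmSpec
#' @export
afSpec <- function(..., seed = 1L) {
  args <- utils::modifyList(
    list(rhythm = "AF", meanRR = 0.6, rrJitter = 0.15, fWaveRate = 420,
         fWaveAmp = 0.2, pAmp = 0, prInterval = 0.16, seed = seed),
    list(...))
  do.call(rhythmSpec, args)
}

#' @rdname rhythmSpec
#' @export
pafSpec <- function(..., seed = 1L) {
  args <- utils::modifyList(
    list(rhythm = "PAF", meanRR = 0.8, rrJitter = 0.05, pAmp = 0.14,
         prInterval = 0.18, prematureProb = 0.15, seed = seed), list(...))
  do.call(rhythmSpec, args)
}

# Gaussian bump evaluated over a sample index window.
gaussBump <- function(t, center, sd, amp) amp * exp(-0.5 * ((t - center) / sd)^2)

# Morphology timing constants (seconds). QRS onset sits qrsOnOff before
# the R peak; the P onset sits 2.5 P-wave sigmas before the P center.
.morph <- list(r_sd = 0.012, q_amp = -0.15, q_off = 0.03, q_sd = 0.008,
               s_amp = -0.25, s_off = 0.03, s_sd = 0.008,
               t_amp = 0.30, t_off = 0.25, t_sd = 0.04,
               p_sd = 0.02, p_on_sigmas = 2.5, qrs_on_off = 0.05)

#' Generate a synthetic single-lead ECG with ground truth
#'
#' Deterministically (given \code{spec@seed}) synthesizes an ECG of the
#' requested rhythm as a sum of Gaussian bumps (P, Q, R, S, T) per beat,
#' plus — for AF — a sinusoidal fibrillatory wave replacing the P waves,
#' plus optional baseline wander, powerline and broadband noise. Returns
#' the signal and the exact fiducials used to draw it.
#'
#' Premature beats (PAF rhythm) shorten the RR to 60\% of \code{meanRR}
#' and are followed by a compensatory pause so that the pair spans two
#' mean cycles.
#'
#' @param spec a [RhythmSpec-class].
#' @param duration signal length in seconds (at least 10).
#' @param fs sampling rate in Hz (at least 100).
#' @return A list with elements \code{signal} ([ECGSignal-class]) and
#'   \code{truth} ([BeatSet-class] of ground-truth fiducials).
#' @examples
#' out <- generateECG(nsrSpec(rrJitter = 0, seed = 1), duration = 30, fs = 250)
#' nBeats(out$truth)
#' @export
generateECG <- function(spec, duration, fs) {
  stopIfNot(is(spec, "RhythmSpec"), "'spec' must be a RhythmSpec")
  validObject(spec)
  stopIfNot(duration >= 10, "'duration' must be at least 10 seconds")
  stopIfNot(fs >= 100, "'fs' must be at least 100 Hz")
  withLocalSeed(spec@seed, {
    m <- .morph
    ## ---- beat schedule -------------------------------------------------
    rTimes <- numeric(0)
    types <- character(0)
    tCur <- 0.4
    pendingPause <- FALSE
    while (tCur <= duration - 0.2) {
      rTimes <- c(rTimes, tCur)
      if (pendingPause) {
        rr <- 1.4 * spec@meanRR
        types <- c(types, "normal")
        pendingPause <- FALSE
      } else if (spec@rhythm == "PAF" &&
                 stats::runif(1) < spec@prematureProb) {
        rr <- 0.6 * spec@meanRR
        types <- c(types, "premature")
        pendingPause <- TRUE
      } else {
        rr <- spec@meanRR + stats::rnorm(1, 0, spec@rrJitter)
        types <- c(types, "normal")
      }
      tCur <- tCur + max(rr, 0.3)
    }
    # the type recorded above describes the beat *initiating* the interval;
    # premature beats should be tagged on the early beat itself
    if (length(types) > 1L)
      types <- c("normal", types[-length(types)])
    nBeat <- length(rTimes)
    n <- round(duration * fs)
    tAxis <- (seq_len(n) - 1) / fs
    x <- numeric(n)

    ## ---- per-beat morphology ------------------------------------------
    addBump <- function(x, center, sd, amp) {
      if (amp == 0) return(x)
      lo <- max(1L, floor((center - 4 * sd) * fs) + 1L)
      hi <- min(n, ceiling((center + 4 * sd) * fs) + 1L)
      if (lo > hi) return(x)
      idx <- lo:hi
      x[idx] <- x[idx] + gaussBump(tAxis[idx], center, sd, amp)
      x
    }
    truth <- data.frame(r_idx = numeric(nBeat), qrs_on_idx = numeric(nBeat),
                        p_peak_idx = rep(NA_real_, nBeat),
                        p_on_idx = rep(NA_real_, nBeat),
                        p_absent = rep(spec@rhythm == "AF", nBeat),
                        beat_type = types)
    for (i in seq_len(nBeat)) {
      tr <- rTimes[i]
      x <- addBump(x, tr, m$r_sd, 1.0)
      x <- addBump(x, tr - m$q_off, m$q_sd, m$q_amp)
      x <- addBump(x, tr + m$s_off, m$s_sd, m$s_amp)
      x <- addBump(x, tr + m$t_off, m$t_sd, m$t_amp)
      qrsOn <- tr - m$qrs_on_off
      truth$r_idx[i] <- round(tr * fs)
      truth$qrs_on_idx[i] <- round(qrsOn * fs)
      if (spec@rhythm != "AF" && spec@pAmp > 0) {
        pAmp <- spec@pAmp
        pr <- spec@prInterval
        if (spec@rhythm == "PAF") {
          pAmp <- pAmp * stats::runif(1, 0.85, 1.15)
          pr <- pr + stats::rnorm(1, 0, 0.008)
        }
        if (types[i] == "premature") pAmp <- 0.8 * pAmp
        pOn <- qrsOn - pr
        pCenter <- pOn + m$p_on_sigmas * m$p_sd
        x <- addBump(x, pCenter, m$p_sd, pAmp)
        truth$p_peak_idx[i] <- round(pCenter * fs)
        truth$p_on_idx[i] <- round(pOn * fs)
      }
    }

    ## ---- atrial f waves and noise -------------------------------------
    if (spec@rhythm == "AF")
      x <- x + spec@fWaveAmp *
        sin(2 * pi * (spec@fWaveRate / 60) * tAxis + stats::runif(1, 0, 2 * pi))
    nz <- spec@noise
    if (nz$baseline_amp > 0)
      x <- x + nz$baseline_amp *
        sin(2 * pi * nz$baseline_freq * tAxis + stats::runif(1, 0, 2 * pi))
    if (nz$powerline_amp > 0)
      x <- x + nz$powerline_amp *
        sin(2 * pi * nz$powerline_freq * tAxis + stats::runif(1, 0, 2 * pi))
    if (nz$white_sigma > 0)
      x <- x + stats::rnorm(n, 0, nz$white_sigma)

    # clip truth indices defensively to the signal range
    truth$qrs_on_idx <- pmax(truth$qrs_on_idx, 0)
    list(signal = ecgSignal(x, fs = fs, source = "synthetic"),
         truth = beatSet(truth, fs = fs, nSamples = n))
  })
}
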