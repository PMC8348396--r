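test_that("bandpass keeps the QRS band and rejects mains interference", {
  t <- (0:4999) / 250
  mains <- ecgSignal(sin(2 * pi * 50 * t), 250)
  inBand <- ecgSignal(sin(2 * pi * 10 * t), 250)
  rms <- function(x) sqrt(mean(x^2))
  outM <- bandpassECG(mains)
  outB <- bandpassECG(inBand)
  expect_lt(rms(samples(outM)), 0.10 * rms(samples(mains)))
  expect_lt(abs(rms(samples(outB)) - rms(samples(inBand))),
            0.20 * rms(samples(inBand)))
  expect_equal(length(samples(outM)), length(samples(mains)))
  # zero in, zero out
  z <- bandpassECG(ecgSignal(rep(0, 1000), 250))
  expect_true(all(samples(z) == 0))
  # cutoff at/above Nyquist rejected
  expect_error(bandpassECG(ecgSignal(rnorm(500), 25)), "Nyquist")
})

test_that("derivative, squaring and integration follow their definitions", {
  expect_equal(samples(squareECG(ecgSignal(c(-2, 3), 250))), c(4, 9))
  # derivative of a constant is identically zero
  d <- derivativeECG(ecgSignal(rep(3.5, 100), 250))
  expect_true(all(samples(d) == 0))
  # impulse through the N-sample moving-window integrator
  N <- round(0.150 * 200)
  imp <- ecgSignal(c(rep(0, 50), 1, rep(0, 100)), 200)
  y <- samples(mwiECG(imp, 0.150))
  expect_equal(sum(y > 0), N)
  expect_true(all(abs(y[y > 0] - 1 / N) < 1e-12))
  expect_error(mwiECG(ecgSignal(rnorm(100), 250), window = 0.001),
               "at least one sample")
})

test_that("clean sinus beats are detected with full sensitivity and precision", {
  out <- fxNSRClean()
  det <- detectRPeaks(out$signal)
  expect_false(isFlagged(det))
  m <- matchRate(rPeaks(det), rPeaks(out$truth), round(0.05 * 250))
  expect_equal(unname(m["se"]), 1)
  expect_equal(unname(m["ppv"]), 1)
  # strictly increasing, refractory respected
  expect_true(!is.unsorted(rPeaks(det), strictly = TRUE))
  expect_true(all(diff(rPeaks(det)) >= round(0.2 * 250)))
})

test_that("detection is idempotent and lands on bandpassed local maxima", {
  out <- fxNSR()
  d1 <- detectRPeaks(out$signal)
  d2 <- detectRPeaks(out$signal)
  expect_identical(beats(d1), beats(d2))
  bp <- samples(bandpassECG(out$signal))
  r1 <- rPeaks(d1) + 1
  interior <- r1[r1 > 1 & r1 < length(bp)]
  expect_true(all(bp[interior] >= bp[interior - 1] &
                    bp[interior] >= bp[interior + 1]))
})

test_that("search-back recovers a beat whose R amplitude was halved", {
  out <- fxNSRClean()
  x <- samples(out$signal)
  tb <- beats(out$truth)
  k <- 30                                   # an interior beat
  r0 <- tb$r_idx[k]
  span <- (r0 - round(0.08 * 250)):(r0 + round(0.08 * 250)) + 1
  x[span] <- 0.5 * x[span]
  det <- detectRPeaks(ecgSignal(x, 250))
  m <- matchRate(rPeaks(det), tb$r_idx, round(0.05 * 250))
  expect_equal(unname(m["se"]), 1)
  expect_true(any(abs(rPeaks(det) - r0) <= round(0.05 * 250)))
})

test_that("degenerate inputs yield flagged, not broken, results", {
  z <- detectRPeaks(ecgSignal(rep(0, 3000), 250))
  expect_true(isFlagged(z))
  expect_equal(nBeats(z), 0)
})

test_that("sensitivity on clean sinus stays above 99% across 20 seeds", {
  ses <- vapply(1:20, function(s) {
    out <- generateECG(nsrSpec(seed = s), 60, 250)
    det <- detectRPeaks(out$signal)
    matchRate(rPeaks(det), rPeaks(out$truth), round(0.05 * 250))["se"]
  }, numeric(1))
  expect_true(all(ses >= 0.99))
})

test_that("sinus P waves are delineated close to the generator's truth", {
  out <- fxNSRClean()
  det <- detectRPeaks(out$signal)
  del <- delineateBeats(out$signal, rPeaks(det))
  b <- beats(del); tb <- beats(out$truth)
  hits <- 0; tot <- 0
  for (i in which(!b$p_absent)) {
    j <- which.min(abs(tb$r_idx - b$r_idx[i]))
    if (!is.na(tb$p_peak_idx[j])) {
      tot <- tot + 1
      hits <- hits + (abs(b$p_peak_idx[i] - tb$p_peak_idx[j]) <=
                        round(0.03 * 250))
    }
  }
  expect_gt(tot / nrow(b), 0.9)       # nearly every beat got a P call
  expect_gte(hits / tot, 0.95)        # and it sits within 30 ms of truth
  # ordering invariant on every delineated beat
  ok <- !b$p_absent
  expect_true(all(b$p_on_idx[ok] < b$p_peak_idx[ok] &
                    b$p_peak_idx[ok] < b$qrs_on_idx[ok] &
                    b$qrs_on_idx[ok] <= b$r_idx[ok]))
})

test_that("fibrillating signals are marked P-absent", {
  out <- fxAF()
  det <- detectRPeaks(out$signal)
  del <- delineateBeats(out$signal, rPeaks(det))
  expect_gte(mean(beats(del)$p_absent), 0.80)
})

test_that("a near-single-beat signal delineates without P annotations", {
  one <- generateECG(nsrSpec(rrJitter = 0, seed = 1), 10, 250)
  r <- rPeaks(one$truth)[1]
  # slice starting just before the R so the P search window of the
  # only beat falls off the record start
  sig <- windowECG(one$signal, r - 12, r + 88)
  del <- delineateBeats(sig, 12)
  expect_equal(nBeats(del), 1)
  expect_true(all(beats(del)$p_absent))
})
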