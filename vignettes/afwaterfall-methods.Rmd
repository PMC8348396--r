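---
title: "Methods: the waterfall AF classifier and its surrounding pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the waterfall AF classifier and its surrounding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science and the engineering decisions inside
`afwaterfall`: the two-stage model, the signal-processing pipeline that
feeds it, the synthetic data the package tests itself on, and the
numerical choices that were genuinely open.

## 1. The two-stage waterfall model

Atrial fibrillation (AF) produces two independent ECG signatures: an
irregularly irregular ventricular response — erratic RR intervals — and
the replacement of atrial P waves by continuous fibrillatory (f) waves
of 350–600 cycles/min and roughly 0.05–0.50 mV. Paroxysmal AF (PAF) is
a different problem: between episodes the rhythm is sinus, and the
pre-episode ECG differs from a healthy one only in subtle P-wave
morphology and rhythm perturbations (notably premature beats).

The package therefore composes two binary RBF-SVM classifiers in
series ("waterfall"):

* **Stage 1 — diagnosis (AF vs N).** Six RR-interval statistics per
  segment (`rr_std`, `rr_mean`, `rr_max`, `rr_rms`, `rr_cha`,
  `rr_len`). RR features deliberately exclude atrial information: they
  are robust across recording hardware and lead systems, whereas
  P-wave shape is not.
* **Stage 2 — prediction (PAF vs N).** Runs only on segments stage 1
  calls N. Uses all 14 features: the six RR statistics plus mean PR
  interval, mean P amplitude, and six level-4 bior5.5 wavelet
  summaries of the P band.

Both stages evaluate
\(f(x) = \operatorname{sign}\left(\sum_i \alpha_i^* y_i e^{-\gamma\|x_i-x\|^2} + b^*\right)\)
explicitly from stored support vectors (`svmDecide()`), with the
quadratic program solved by libsvm behind `svmTrain()`. The decision
threshold stays at 0 — no cost-sensitive reweighting — and a tie
(score exactly 0) goes to the positive class by convention.

Assumptions worth stating: segments are single-lead, uniformly
sampled, and long enough to carry at least three beats; the two stages
are trained on their own populations (stage 2 never sees AF segments);
and PAF-precursor segments count as N for stage 1 (they are sinus
rhythm, not AF onset — `trainHybrid(pafAsN = FALSE)` excludes them
instead). Missing P-dependent features at stage 2 (typical for
segments without delineated P waves) are imputed with the stage-2
training means and flagged with a warning.

## 2. Pre-processing and delineation

The QRS detector follows the classic transformation chain: a 5–15 Hz
zero-phase Butterworth bandpass (QRS emphasis; applied with
`filtfilt`, so no phase distortion), a five-point derivative kernel
\((-1,-2,0,2,1)/8\), elementwise squaring, and a 150 ms causal
moving-window integrator. The band edges, kernel and window are the
canonical values for this chain. On the integrated signal, adaptive
thresholds separate QRS peaks from noise peaks:

* accepted peaks update the signal level by
  \(0.125\,\text{peak} + 0.875\,\text{level}\); rejected peaks update
  the noise level analogously;
* the decision threshold is \(\text{noise} + 0.25(\text{signal} -
  \text{noise})\);
* a 200 ms refractory period drops the lower of two colliding peaks;
* any inter-peak gap exceeding 1.66 × (running mean of the last eight
  RR intervals) is re-scanned at half the threshold (search-back),
  which recovers attenuated beats;
* accepted integrator peaks are mapped back to the nearest local
  maximum of the bandpassed signal, so every reported R index is a
  true local maximum.

Fewer than two detected beats yields a *flagged* result and downstream
RR features refuse the segment rather than fabricating statistics.

**Delineation.** The QRS onset is the last sample before the R
upstroke where the slope of a 0.5–40 Hz cleaned copy falls below 10%
of the beat's maximum upstroke slope. The P search then works on a
heavily smoothed copy: the QRS complexes are first blanked (linearly
bridged over \([R-60\,\text{ms}, R+100\,\text{ms}]\)) so the R wave
cannot leak a skirt into the window, and the result is low-passed at
4.5 Hz (order 4, zero phase), which attenuates 350–600 cycles/min
f waves by roughly two orders of magnitude while the much
lower-frequency P hump survives. The window is
\([QRS_{on}-240\,\text{ms},\,QRS_{on}-40\,\text{ms}]\), with the left
edge additionally kept at least 350 ms after the previous R peak so
the previous T wave stays outside. A beat is marked P-absent when the
window's argmax sits on an edge, when its prominence over the leading
40 ms baseline falls below 0.025 mV, or when the window's
*fibrillatory ripple* — the standard deviation of the 4.5–40 Hz
residual — exceeds 0.06 mV. The ripple veto is the clinically
meaningful discriminator: a pre-episode P wave of reduced amplitude
and a smoothed f-wave hump can have identical prominence, but only
fibrillation fills the window with high-frequency oscillation.

## 3. Features

* `rr_std` uses the sample (n−1) standard deviation; `rr_rms` is
  literally the RMS of the RR series (name-faithful; the HRV
  convention RMSSD is available via `rrFeatures(rms = "rmssd")`);
  `rr_cha` is the range (max − min) and `rr_len` the RR count — the
  two quantities a name alone does not pin down, so both definitions
  are stated here and in the help pages.
* PR is onset-to-onset, \(|QRS_{on} - P_{on}|\), averaged over beats
  with a P call; `prInterval(from = "peak")` gives the peak-to-peak
  variant. P amplitude is \(amp_P - amp_{P_{on}}\).
* The P band for the wavelet features is, by default, the
  concatenation of the per-beat P windows; `pBand = "whole"` instead
  decomposes the entire record, for workflows that prefer a
  whole-signal decomposition. Five decomposition levels are computed
  and the level-4 approximation and detail vectors — whose band
  corresponds to P-wave frequencies at 250 Hz sampling — are
  summarized. The three scalars per coefficient vector are (mean,
  standard deviation, energy): scale-covariant, order-free summaries
  (the transform halves vector lengths, so raw coefficients are not
  comparable across segment durations; these summaries are).
* The feature scaler is a z-score with a *population* (divisor n)
  standard deviation, so a two-point training set \(\{1, 3\}\) maps
  exactly to \(\{-1, +1\}\); a zero-spread feature is clamped to unit
  spread (scaling constants to zero) with a warning. The scaler is
  frozen on the training rows and reused verbatim at prediction time —
  inside cross-validation it is refit per training fold, never on the
  held-out fold.

The bior5.5 filter bank is implemented in-package (analysis/synthesis
with half-sample symmetric extension). The coefficients are the
standard published values for this basis; tests verify perfect
reconstruction below 1e−8 and agreement with an independent reference
transform frozen into the test file.

## 4. Hyperparameter tuning

Both tuners maximize stratified k-fold cross-validated accuracy (folds
fixed by seed, identical for both tuners in a comparison, scaler fit
inside each fold).

The quantum-behaved swarm moves each particle by
\[
x(t+1) = p \pm \lambda\,|Mbest - x(t)|\,\ln(1/u), \qquad
p = \varphi\,pbest + (1-\varphi)\,gbest,
\]
taking \(+\) when a uniform draw \(k \ge 0.5\). Three choices here were
genuinely open and are resolved as follows:

* the local attractor \(p\) uses the standard convex combination with
  \(\varphi \sim U(0,1)\) drawn per particle and iteration;
* the kernel of the update is read with an absolute value,
  \(|Mbest - x|\) — without it the \(\pm\) branch would be redundant;
* out-of-bounds moves are clamped to the search box (not reflected),
  the simplest contract that keeps every position in bounds.

Search runs in \((\log_{10} C, \log_{10} \gamma)\) over \([-3, 4]^2\)
(0.001–10,000): hyperparameters act multiplicatively, so exploration
should be scale-free. Defaults are 20 particles and 30 iterations —
the first iteration evaluates the seeded swarm, so the budget is
exactly 600 fitness evaluations. λ decays linearly from 1.0 to 0.5
(`lambdaSchedule()`); setting `lambdaMax = lambdaMin` gives the
fixed-coefficient variant. A plateau with no global-best improvement
for `patience` iterations stops early. The grid baseline evaluates the
full Cartesian grid and breaks ties toward smaller C, then smaller γ
(stronger regularization preferred).

## 5. The synthetic data generator

The generator is the package's test bed and stands in for clinical
recordings. Beats are sums of Gaussian bumps (P, Q, R, S, T) with
fixed morphology timing; rhythms differ in their RR process and atrial
activity:

* **NSR**: mean RR 0.8 s, jitter 0.03 s, P amplitude 0.2 mV, PR
  0.16 s — textbook resting sinus values.
* **AF**: mean RR 0.6 s (the typical rapid ventricular response),
  jitter 0.15 s (five times sinus, reflecting the irregular response),
  no P waves, plus a single sinusoid at `fWaveRate`/60 Hz (default
  420 cycles/min, 0.2 mV) standing in for f waves. A single sinusoid —
  rather than stochastic atrial wavelets — keeps spectral assertions
  testable; the constructor enforces the clinical 350–600 cycles/min
  and 0.05–0.50 mV ranges unless overridden.
* **PAF precursor**: sinus rhythm with premature beats
  (probability 0.15 per beat; RR shortened to 60% of the mean followed
  by a compensatory pause totalling two cycles), P amplitude reduced
  to 0.14 mV with ±15% per-beat variability, PR lengthened to 0.18 s
  with 8 ms jitter. These effect sizes are free parameters of the
  model — no quantitative precursor morphology is established — and
  were chosen once as plausible perturbations large enough to be
  learnable yet far from the trivially separable regime.

Optional noise adds sinusoidal baseline wander (0.3 Hz), mains
interference (50 Hz) and white noise. Unit tests run noise-free;
integration-style checks switch it on.

What passing tests on this generator does and does not show: it
validates the *mechanics* — detector logic, feature arithmetic,
ensemble bookkeeping, tuner behaviour — under controlled truth. It
does not establish clinical performance: real AF has stochastic
f waves, ectopy, artifacts and inter-patient morphology variation far
beyond Gaussian-bump beats, and real PAF precursors are weaker and
less consistent than the synthetic ones. Headline accuracies on the
synthetic benchmark are therefore ceilings, not estimates.

## 6. The report digitizer

Clinical ECG archives are often only rasterized reports. The digitizer
inverts the rendering: grayscale conversion and gamma transform
(default γ = 0.5; brightening mid-tones pulls the faint calibration
grid toward the background, which is what makes the subsequent
threshold isolate the ink — the "improvement" over plain Otsu *is*
this gamma pre-transform), Otsu's threshold (maximizing between-class
variance, ties to the lowest level, binarizing ink as
below-threshold), grid removal, column-wise trace extraction, and
affine calibration (default 25 mm/s, 10 mm/mV — the clinical standard
scales).

Decisions that were open:

* **Grid removal** uses the exact mask for rendered fixtures and
  otherwise detects grid lines as rows/columns whose foreground
  fraction exceeds 0.95. The high default is deliberate: grid lines
  cross the whole sheet including margins, while a flat ECG baseline
  stops at the trace ends — a lower threshold would delete the
  baseline of a quiet signal as if it were a grid line.
* **Column statistic**: the centroid of each column's ink (robust to
  line thickness), not the topmost pixel.
* **Breakpoints** (columns emptied where curve and grid crossed) are
  filled by linear interpolation between flanking columns; more than
  20% empty columns rejects the digitization as unreliable rather
  than guessing.
* The renderer splits each vertical connector stroke between the two
  columns it joins, so column centroids reproduce the source within
  one pixel RMS on smooth signals; steep QRS strokes still lose a
  little apex amplitude to centroid averaging, which is why round-trip
  correlation is ~0.99 rather than 1.

## 7. Evaluation metrics

`binaryMetrics()` computes SE = TP/(TP+FN), SP = TN/(TN+FP),
Acc = (TP+TN)/total from a 2×2 actual-by-predicted table; zero
denominators yield NA rather than a silent 0 or 1. For three classes,
`ovrMetrics()` collapses one-vs-rest: for class c, TP is the diagonal
cell, FN the rest of c's row, FP the rest of c's column, and TN
everything else — including off-diagonal confusions among the other
classes, which is what the one-vs-rest definition implies. Display
rounding is half-up to one decimal (`asPercent(0.98750)` → 98.8); raw
rationals are kept internally.

An errata note: published tables of this kind are not always
self-consistent. The package's own checks therefore target only
matrix-derivable quantities — the two-class diagnosis table
(SE = SP = Acc = 357/360), the clinical two-class prediction table
(SE = 65/69) and the three-class fusion table under the one-vs-rest
definitions (PAF SE = 37/40, AF SE = 39/40, SP = 79/80,
Acc = 118/120). A three-label PAF specificity/accuracy pair sometimes
quoted alongside that fusion table (90% / 90.8%) does not follow from
the table under the same definitions (which give 92.5% / 92.5%) and is
deliberately not a target.

## 8. Problem sizes and known limitations

The shipped benchmarks use 5-minute segments at 250 Hz, 40 segments
per class for the ensemble benchmark, 60-second strips for detector
checks, and 10-second strips for digitizer round trips — sizes chosen
so the whole suite exercises every code path at full fidelity while
remaining comfortable to run interactively.

Known limitations: single-lead only; no atrial flutter or junctional
rhythms in the generator or the label vocabulary; T waves are not
delineated; the WFDB reader covers headers, formats 16 and 212 and
core MIT annotations (enough for the public AF archives) but not the
full format zoo; the digitizer assumes an axis-aligned scan (no
de-skewing) and known calibration scales; and all reported accuracies
are synthetic-benchmark ceilings, not clinical estimates.
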