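# Shared fixtures, computed lazily and cached for the whole run.

.fx <- new.env(parent = emptyenv())

fxGet <- function(key, build) {
  if (!exists(key, envir = .fx)) assign(key, build(), envir = .fx)
  get(key, envir = .fx)
}

# one clean zero-jitter NSR minute (detection/delineation fixtures)
fxNSRClean <- function() fxGet("nsr_clean", function()
  generateECG(nsrSpec(rrJitter = 0, seed = 1), 60, 250))

fxNSR <- function() fxGet("nsr", function()
  generateECG(nsrSpec(seed = 2), 60, 250))

fxAF <- function() fxGet("af", function()
  generateECG(afSpec(seed = 2), 60, 250))

# match detected 0-based indices against truth with a tolerance (samples)
matchRate <- function(detected, truth, tolSamples) {
  if (!length(detected) || !length(truth)) return(c(se = 0, ppv = 0))
  se <- mean(vapply(truth, function(r)
    any(abs(detected - r) <= tolSamples), logical(1)))
  ppv <- mean(vapply(detected, function(d)
    any(abs(truth - d) <= tolSamples), logical(1)))
  c(se = se, ppv = ppv)
}

# brute-force Otsu oracle: naive exhaustive scan over all 256 split
# points, computing class moments directly from the histogram
otsuBruteForce <- function(h) {
  lv <- 0:255
  best <- -Inf; bestT <- NA
  for (t in 1:255) {                 # upper class = levels >= t
    lo <- lv < t; hi <- !lo
    w0 <- sum(h[lo]); w1 <- sum(h[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[lo] * lv[lo]) / w0
    mu1 <- sum(h[hi] * lv[hi]) / w1
    v <- (w0 / sum(h)) * (w1 / sum(h)) * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; bestT <- t }
  }
  bestT
}

# independent re-statement of the quantum position update
qpsoOracle <- function(x, pbest, gbest, mbest, lambda, u, k, phi) {
  p <- phi * pbest + (1 - phi) * gbest
  if (k >= 0.5) p + lambda * abs(mbest - x) * log(1 / u)
  else          p - lambda * abs(mbest - x) * log(1 / u)
}
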