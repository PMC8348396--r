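# Discrete wavelet transform with the bior5.5 biorthogonal basis.
#
# The filter bank below is the standard published bior5.5 (biorthogonal
# 5.5) analysis/synthesis quadruple. Signals are extended by half-sample
# symmetric reflection before convolution, so analysis followed by
# synthesis reconstructs the input exactly (to floating-point error).

.bior55 <- list(
  dec_lo = c(0, 0, 0.03968708834740544, 0.007948108637240322,
             -0.05446378846823691, 0.34560528195603346,
             0.7366601814282105, 0.34560528195603346,
             -0.05446378846823691, 0.007948108637240322,
             0.03968708834740544, 0),
  dec_hi = c(-0.013456709459118716, -0.002694966880111507,
             0.13670658466432914, -0.09350469740093886,
             -0.47680326579848425, 0.8995061097486484,
             -0.47680326579848425, -0.09350469740093886,
             0.13670658466432914, -0.002694966880111507,
             -0.013456709459118716, 0),
  rec_lo = c(0.013456709459118716, -0.002694966880111507,
             -0.13670658466432914, -0.09350469740093886,
             0.47680326579848425, 0.8995061097486484,
             0.47680326579848425, -0.09350469740093886,
             -0.13670658466432914, -0.002694966880111507,
             0.013456709459118716, 0),
  rec_hi = c(0, 0, 0.03968708834740544, -0.007948108637240322,
             -0.05446378846823691, -0.34560528195603346,
             0.7366601814282105, -0.34560528195603346,
             -0.05446378846823691, -0.007948108637240322,
             0.03968708834740544, 0))

# full convolution (length n + length(k) - 1)
convFull <- function(x, k) stats::convolve(x, rev(k), type = "open")

#' Single-level bior5.5 analysis / synthesis
#'
#' \code{dwtBior55} computes one analysis level: the input is extended
#' by half-sample symmetric reflection, convolved with the analysis
#' filters, and downsampled by two. \code{idwtBior55} inverts it.
#'
#' @param x numeric signal.
#' @param cA,cD approximation and detail coefficients from
#'   \code{dwtBior55}.
#' @param n original signal length to restore.
#' @return \code{dwtBior55}: list with \code{cA} and \code{cD}, each of
#'   length \code{floor((length(x) + 11) / 2)}; \code{idwtBior55}: the
#'   reconstructed signal of length \code{n}.
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 50))
#' d <- dwtBior55(x)
#' max(abs(idwtBior55(d$cA, d$cD, length(x)) - x)) < 1e-8
#' @export
dwtBior55 <- function(x) {
  L <- length(.bior55$dec_lo)
  n <- length(x)
  stopIfNot(n >= 2, "signal too short for analysis")
  # half-sample symmetric extension by L-1 samples on each side,
  # expressed through a triangle-wave index map so it is valid for any
  # signal length (repeated reflection for very short inputs)
  symIdx <- function(k) {            # 0-based position -> 0-based index
    p <- k %% (2 * n)
    ifelse(p < n, p, 2 * n - 1 - p)
  }
  ext <- x[symIdx(seq.int(-(L - 1), n + L - 2)) + 1]
  a <- convFull(ext, .bior55$dec_lo)
  d <- convFull(ext, .bior55$dec_hi)
  # valid region, odd-phase downsampling
  keep <- seq.int(L, length.out = length(x) + L - 1)
  a <- a[keep]; d <- d[keep]
  list(cA = a[seq.int(2, length(a), by = 2)],
       cD = d[seq.int(2, length(d), by = 2)])
}

#' @rdname dwtBior55
#' @export
idwtBior55 <- function(cA, cD, n) {
  L <- length(.bior55$rec_lo)
  stopIfNot(length(cA) == length(cD),
            "cA and cD must have equal length")
  up <- function(c) { u <- numeric(2 * length(c)); u[seq.int(1, length(u), 2)] <- c; u }
  s <- convFull(up(cA), .bior55$rec_lo) + convFull(up(cD), .bior55$rec_hi)
  crop <- L - 2
  out <- s[seq.int(crop + 1, length.out = 2 * length(cA) - L + 2)]
  out[seq_len(n)]
}

#' Multi-level bior5.5 decomposition and reconstruction
#'
#' \code{waveDecBior55} applies [dwtBior55()] recursively to the
#' approximation path, keeping every level's approximation and detail
#' vector (so the level-4 coefficients used as frequency-domain ECG
#' features are directly available). \code{waveRecBior55} inverts the
#' full decomposition.
#'
#' @param x numeric signal.
#' @param levels number of analysis levels.
#' @param dec result of \code{waveDecBior55}.
#' @return \code{waveDecBior55}: list with elements \code{cA} (list of
#'   per-level approximation vectors), \code{cD} (list of per-level
#'   detail vectors), \code{lengths} (input length at each level) and
#'   \code{n}; \code{waveRecBior55}: the reconstructed signal.
#' @export
waveDecBior55 <- function(x, levels = 5) {
  stopIfNot(levels >= 1, "'levels' must be at least 1")
  cA <- vector("list", levels); cD <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(cur)
    d <- dwtBior55(cur)
    cA[[l]] <- d$cA; cD[[l]] <- d$cD
    cur <- d$cA
  }
  list(cA = cA, cD = cD, lengths = lens, n = length(x))
}

#' @rdname waveDecBior55
#' @export
waveRecBior55 <- function(dec) {
  levels <- length(dec$cD)
  cur <- dec$cA[[levels]]
  for (l in rev(seq_len(levels)))
    cur <- idwtBior55(cur, dec$cD[[l]], dec$lengths[l])
  cur
}
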