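# Seeded benchmark data builders used by the examples, tests and the
# reproduction script: separable 2-D blobs for the tuner head-to-head,
# and a labeled synthetic segment set for the waterfall ensemble.

#' Two separable Gaussian blobs in the plane
#'
#' @param n points per class.
#' @param sep distance between the class centers.
#' @param sd within-class standard deviation.
#' @param seed integer seed.
#' @return List with \code{x} (data.frame \code{f1}, \code{f2}) and
#'   \code{y} (labels \code{"a"}, \code{"b"}).
#' @export
makeBlobs <- function(n = 60, sep = 4, sd = 1, seed = 1L) {
  withLocalSeed(seed, {
    x <- data.frame(
      f1 = c(stats::rnorm(n, -sep / 2, sd), stats::rnorm(n, sep / 2, sd)),
      f2 = c(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd)))
    list(x = x, y = rep(c("a", "b"), each = n))
  })
}

#' Build a labeled synthetic segment feature table
#'
#' Generates \code{nPerClass} independent ECG segments per rhythm class
#' (N = normal sinus, AF, PAF = pre-episode sinus), runs the full
#' detection / delineation / feature pipeline on each, and returns the
#' combined feature table. Seeds are derived deterministically from
#' \code{seed}, one per segment.
#'
#' @param nPerClass segments per class.
#' @param segSeconds segment duration, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer master seed.
#' @param noise a [noiseSpec()] applied to every segment.
#' @return data.frame of [segmentFeatures()] rows with a \code{label}
#'   column.
#' @export
makeSegmentDataset <- function(nPerClass = 40, segSeconds = 300, fs = 250,
                               seed = 1L, noise = noiseSpec()) {
  specFor <- function(cls, s) switch(cls,
    N = nsrSpec(seed = s, noise = noise),
    AF = afSpec(seed = s, noise = noise),
    PAF = pafSpec(seed = s, noise = noise))
  rows <- list()
  i <- 0L
  for (cls in c("N", "AF", "PAF")) {
    for (k in seq_len(nPerClass)) {
      i <- i + 1L
      out <- generateECG(specFor(cls, childSeed(seed, i)), segSeconds, fs)
      rows[[i]] <- segmentFeatures(out$signal, label = cls)
    }
  }
  do.call(rbind, rows)
}
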