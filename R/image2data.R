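# Digitization of rasterized ECG report images: gamma pre-transform,
# Otsu binarization, grid/curve separation, column-wise trace
# extraction with breakpoint repair, and calibration to millivolts.

# Luma conversion of a ReportImage or HxWx3 array to a matrix.
toGray <- function(img) {
  px <- if (is(img, "ReportImage")) img@pixels else img
  if (length(dim(px)) == 3L)
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  else px
}

#' Gamma transformation of an image's grayscale values
#'
#' Quantizes the grayscale conversion to 8 bits and applies the power
#' transform \code{round(255 * (v/255)^gammaImg)} per pixel. Gamma
#' below 1 brightens mid-tones, pulling the faint calibration grid
#' toward the background before thresholding — which is what makes the
#' subsequent Otsu separation isolate the ink trace.
#'
#' @param img a [ReportImage-class], an \code{HxWx3} array in
#'   \code{[0,1]}, or a grayscale matrix (either \code{[0,1]} or
#'   already 0–255).
#' @param gammaImg positive exponent; 1 is the identity.
#' @return Integer-valued matrix of gamma-corrected levels 0–255.
#' @examples
#' gammaCorrect(matrix(64/255, 1, 1), 0.5)   # 128
#' @export
gammaCorrect <- function(img, gammaImg = 0.5) {
  stopIfNot(gammaImg > 0, "'gammaImg' must be positive")
  g <- toGray(img)
  v <- if (max(g) <= 1) round(255 * g) else round(g)
  matrix(round(255 * (v / 255)^gammaImg), nrow(v), ncol(v))
}

#' Otsu threshold of a 256-bin grayscale histogram
#'
#' Returns the level maximizing the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0 - \mu_1)^2} over all splits
#' \{levels < t\} vs \{levels >= t\}; ties break to the lowest level.
#' The returned threshold is the first level of the upper class, so
#' binarization is \code{pixel >= threshold}.
#'
#' @param h integer vector of 256 counts (levels 0–255), e.g.
#'   \code{tabulate(gray + 1, 256)}.
#' @return The threshold level (0–255). A single-valued image returns
#'   that value with attribute \code{degenerate = TRUE}.
#' @export
otsuThreshold <- function(h) {
  stopIfNot(length(h) == 256, "'h' must have 256 bins")
  stopIfNot(sum(h) > 0, "histogram is empty")
  lv <- 0:255
  nz <- which(h > 0)
  if (length(nz) == 1L) {
    t <- lv[nz]
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  total <- sum(h)
  w0 <- cumsum(h) / total                # mass of levels <= t
  mu0 <- cumsum(h * lv) / pmax(cumsum(h), 1)
  muT <- sum(h * lv) / total
  w1 <- 1 - w0
  mu1 <- (muT - w0 * mu0) / ifelse(w1 > 0, w1, 1)
  sigmaB <- w0 * w1 * (mu0 - mu1)^2      # split after level t = lv
  sigmaB[w0 == 0 | w1 == 0] <- -Inf
  # threshold = first level of the upper class
  lv[which.max(sigmaB)] + 1L
}

#' Separate the ECG curve from the calibration grid
#'
#' Removes grid pixels from a binarized (foreground = TRUE) image.
#' When the true grid mask is known (synthetic fixtures) it is
#' subtracted directly; otherwise grid lines are detected as long
#' straight runs — rows/columns whose foreground fraction exceeds
#' \code{lineFrac}. The default is deliberately close to 1: grid lines
#' cross the entire sheet including its margins, whereas an ECG
#' baseline, however flat, stops at the trace ends — this keeps a flat
#' trace from being mistaken for a grid line. Removal where curve and
#' grid intersect creates breakpoints, repaired later by
#' [extractTrace()].
#'
#' @param binary logical matrix, TRUE = foreground.
#' @param gridMask optional logical matrix of known grid pixels.
#' @param lineFrac row/column foreground fraction above which a line is
#'   declared part of the grid.
#' @return Logical matrix of curve pixels.
#' @export
separateCurve <- function(binary, gridMask = NULL, lineFrac = 0.95) {
  stopIfNot(is.matrix(binary), "'binary' must be a matrix")
  binary <- binary > 0
  if (is.null(gridMask)) {
    gridMask <- matrix(FALSE, nrow(binary), ncol(binary))
    gridMask[rowMeans(binary) > lineFrac, ] <- TRUE
    gridMask[, colMeans(binary) > lineFrac] <- TRUE
  }
  binary & !gridMask
}

#' Column-wise trace extraction with breakpoint repair
#'
#' Walks the curve image column by column: each column's trace
#' position is the centroid row of its foreground pixels; empty
#' columns inside the trace domain are breakpoints, filled by linear
#' interpolation between the nearest flanking columns. Digitization is
#' rejected when more than \code{maxMissing} of the in-domain columns
#' are empty.
#'
#' @param curve logical matrix of curve pixels (TRUE = ink).
#' @param maxMissing maximum tolerated fraction of empty columns.
#' @return List: \code{position} (per-column row, NA outside the
#'   domain), \code{domain} (first and last non-empty column),
#'   \code{breakpoints} (logical, repaired columns).
#' @export
extractTrace <- function(curve, maxMissing = 0.2) {
  stopIfNot(is.matrix(curve), "'curve' must be a matrix")
  curve <- curve > 0
  counts <- colSums(curve)
  rowsIdx <- seq_len(nrow(curve))
  pos <- ifelse(counts > 0, as.numeric(crossprod(rowsIdx, curve)) /
                  pmax(counts, 1), NA_real_)
  nonEmpty <- which(counts > 0)
  stopIfNot(length(nonEmpty) >= 2, "no trace found in the image")
  dom <- range(nonEmpty)
  inDom <- seq(dom[1], dom[2])
  missing <- is.na(pos[inDom])
  if (mean(missing) > maxMissing)
    stop(sprintf(
      "digitization rejected as unreliable: %.1f%% of columns empty",
      100 * mean(missing)), call. = FALSE)
  repaired <- pos
  if (any(missing))
    repaired[inDom][missing] <-
      stats::approx(inDom[!missing], pos[inDom][!missing],
                    xout = inDom[missing])$y
  bp <- rep(FALSE, length(pos))
  bp[inDom][missing] <- TRUE
  list(position = repaired, domain = dom, breakpoints = bp)
}

#' Map an extracted trace to a calibrated, resampled ECG signal
#'
#' Columns become time through the paper speed
#' (\code{px_per_mm * mm_per_s} pixels per second), rows become
#' millivolts through the amplitude scale and baseline row, and the
#' irregular column series is resampled to \code{fsOut} by linear
#' interpolation.
#'
#' @param tc trace list from [extractTrace()].
#' @param cal calibration list (\code{px_per_mm}, \code{mm_per_s},
#'   \code{mm_per_mV}, \code{baseline_row}, \code{x0}).
#' @param fsOut output sampling rate, Hz.
#' @return An [ECGSignal-class] with \code{source = "digitized"}.
#' @export
calibrateTrace <- function(tc, cal, fsOut = 250) {
  need <- c("px_per_mm", "mm_per_s", "mm_per_mV", "baseline_row", "x0")
  stopIfNot(all(need %in% names(cal)),
            paste("calibration must contain:", paste(need, collapse = ", ")))
  cols <- seq(tc$domain[1], tc$domain[2])
  tCols <- (cols - cal$x0) / (cal$px_per_mm * cal$mm_per_s)
  vCols <- (cal$baseline_row - tc$position[cols]) /
    (cal$px_per_mm * cal$mm_per_mV)
  tOut <- seq(max(0, tCols[1]), tCols[length(tCols)], by = 1 / fsOut)
  v <- stats::approx(tCols, vCols, xout = tOut, rule = 2)$y
  ecgSignal(v, fsOut, source = "digitized")
}

#' Digitize a rasterized ECG report image end to end
#'
#' Gamma transform, Otsu binarization (ink = levels below the
#' threshold), curve/grid separation, column-wise extraction with
#' breakpoint repair, and calibration, in one call.
#'
#' @param img a [ReportImage-class] (its stored calibration is used).
#' @param gammaImg gamma exponent for [gammaCorrect()].
#' @param fsOut output sampling rate, Hz.
#' @param gridMask optional known grid mask forwarded to
#'   [separateCurve()].
#' @return An [ECGSignal-class].
#' @examples
#' src <- generateECG(nsrSpec(seed = 5), 10, 250)$signal
#' img <- renderReport(src)
#' dig <- digitizeReport(img)
#' cor(samples(src), samples(dig)[seq_along(samples(src))])
#' @export
digitizeReport <- function(img, gammaImg = 0.5, fsOut = 250,
                           gridMask = NULL) {
  stopIfNot(is(img, "ReportImage"), "'img' must be a ReportImage")
  g <- gammaCorrect(img, gammaImg)
  thr <- otsuThreshold(tabulate(g + 1, 256))
  binary <- g < thr                      # ink is dark
  curve <- separateCurve(binary, gridMask)
  tc <- extractTrace(curve)
  calibrateTrace(tc, img@calibration, fsOut)
}
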