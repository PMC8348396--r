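#' Render an ECG signal as a rasterized clinical report strip
#'
#' Draws the trace in dark ink over a standard calibration grid (fine
#' lines every 1 mm, coarse every 5 mm) at the usual clinical scales
#' (default 25 mm/s, 10 mm/mV), returning the image together with the
#' affine calibration used — so a digitization can be scored against
#' the source signal. The vertical drawing range is fixed at ±2 mV
#' around the baseline.
#'
#' @param sig an [ECGSignal-class].
#' @param pxPerMm raster resolution, pixels per millimetre (at least 2).
#' @param mmPerS paper speed, mm per second.
#' @param mmPerMV amplitude scale, mm per millivolt.
#' @param grid \code{"standard"} for the 1 mm / 5 mm grid, \code{"none"}
#'   for a plain white background.
#' @param lineWidth trace thickness in pixels.
#' @param maxWidthPx reject signals whose rendering would exceed this
#'   width (memory guard).
#' @return A [ReportImage-class]. Logical \code{grid} and \code{trace}
#'   masks (for fixture-based tests) are attached and retrievable with
#'   [reportLayers()].
#' @examples
#' sig <- generateECG(nsrSpec(seed = 1), 10, 250)$signal
#' img <- renderReport(sig)
#' dim(img@pixels)
#' @export
renderReport <- function(sig, pxPerMm = 4, mmPerS = 25, mmPerMV = 10,
                         grid = c("standard", "none"), lineWidth = 2,
                         maxWidthPx = 20000) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  stopIfNot(pxPerMm >= 2, "'pxPerMm' must be at least 2")
  grid <- match.arg(grid)
  marginMm <- 5
  durS <- duration(sig)
  widthMm <- durS * mmPerS + 2 * marginMm
  widthPx <- ceiling(widthMm * pxPerMm)
  if (widthPx > maxWidthPx)
    stop(sprintf(
      "signal too long to render: requires %d px width (limit %d); %s",
      widthPx, maxWidthPx,
      "raise 'maxWidthPx' or render a shorter strip"), call. = FALSE)
  vRange <- 2                     # +/- mV drawn
  heightMm <- 2 * vRange * mmPerMV + 2 * marginMm
  heightPx <- ceiling(heightMm * pxPerMm)

  x0 <- marginMm * pxPerMm + 1          # 1-based column of t = 0
  baselineRow <- round(heightPx / 2)    # 1-based row of 0 mV

  px <- array(1, dim = c(heightPx, widthPx, 3))
  gridMask <- matrix(FALSE, heightPx, widthPx)
  if (grid == "standard") {
    mmCols <- round(seq(0, widthMm, by = 1) * pxPerMm) + 1L
    mmRows <- round(seq(0, heightMm, by = 1) * pxPerMm) + 1L
    mmCols <- mmCols[mmCols >= 1 & mmCols <= widthPx]
    mmRows <- mmRows[mmRows >= 1 & mmRows <= heightPx]
    coarseCols <- mmCols[(seq_along(mmCols) - 1L) %% 5L == 0L]
    coarseRows <- mmRows[(seq_along(mmRows) - 1L) %% 5L == 0L]
    fine <- c(1, 0.78, 0.78); coarse <- c(0.93, 0.45, 0.45)
    for (ch in 1:3) {
      px[, mmCols, ch] <- fine[ch]
      px[mmRows, , ch] <- fine[ch]
      px[, coarseCols, ch] <- coarse[ch]
      px[coarseRows, , ch] <- coarse[ch]
    }
    gridMask[, mmCols] <- TRUE
    gridMask[mmRows, ] <- TRUE
  }

  ## trace: per pixel column, interpolate the signal at the column's
  ## time, then connect to the previous column's row with a vertical run
  traceMask <- matrix(FALSE, heightPx, widthPx)
  tSig <- (seq_along(samples(sig)) - 1) / fs(sig)
  cols <- x0:min(widthPx, x0 + ceiling(durS * mmPerS * pxPerMm))
  tCols <- (cols - x0) / (pxPerMm * mmPerS)
  vCols <- stats::approx(tSig, samples(sig), xout = pmin(tCols, max(tSig)),
                         rule = 2)$y
  rows <- round(baselineRow - vCols * mmPerMV * pxPerMm)
  rows <- pmin(pmax(rows, 1L), heightPx)
  halfLo <- floor((lineWidth - 1) / 2)
  halfHi <- ceiling((lineWidth - 1) / 2)
  nc <- length(cols)
  for (j in seq_len(nc)) {
    ## each column owns its half of the connectors to both neighbours,
    ## so steep strokes split evenly between adjacent columns
    midPrev <- if (j > 1) round((rows[j - 1] + rows[j]) / 2) else rows[j]
    midNext <- if (j < nc) round((rows[j + 1] + rows[j]) / 2) else rows[j]
    lo <- min(midPrev, midNext, rows[j])
    hi <- max(midPrev, midNext, rows[j])
    lo <- max(1L, lo - halfLo); hi <- min(heightPx, hi + halfHi)
    traceMask[lo:hi, cols[j]] <- TRUE
  }
  ink <- c(0.08, 0.08, 0.08)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[traceMask] <- ink[ch]
    px[, , ch] <- plane
  }

  img <- new("ReportImage", pixels = px,
             calibration = list(px_per_mm = pxPerMm, mm_per_s = mmPerS,
                                mm_per_mV = mmPerMV,
                                baseline_row = baselineRow, x0 = x0,
                                fs = fs(sig)))
  attr(img@calibration, "layers") <-
    list(grid = gridMask, trace = traceMask)
  img
}

#' Retrieve the renderer's ground-truth pixel layers
#'
#' @param img a [ReportImage-class] produced by [renderReport()].
#' @return A list with logical matrices \code{grid} and \code{trace}, or
#'   \code{NULL} for images that were read from disk.
#' @export
reportLayers <- function(img) attr(img@calibration, "layers")

#' Write a ReportImage to a PNG file
#'
#' @param img a [ReportImage-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeReportPNG <- function(img, path) {
  stopIfNot(is(img, "ReportImage"), "'img' must be a ReportImage")
  png::writePNG(img@pixels, path)
  invisible(path)
}

#' Read a 3-channel PNG report image
#'
#' @param path PNG file path.
#' @param calibration optional calibration list (see
#'   [ReportImage-class]); defaults to the clinical standard
#'   25 mm/s, 10 mm/mV at 4 px/mm with the baseline at mid-height.
#' @return A [ReportImage-class].
#' @export
readReportPNG <- function(path, calibration = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (is.null(calibration))
    calibration <- list(px_per_mm = 4, mm_per_s = 25, mm_per_mV = 10,
                        baseline_row = round(nrow(px) / 2), x0 = 1)
  new("ReportImage", pixels = px, calibration = calibration)
}
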