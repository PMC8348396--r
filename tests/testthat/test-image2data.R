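test_that("gamma transformation follows the 8-bit power law", {
  expect_equal(gammaCorrect(matrix(64 / 255, 1, 1), 0.5)[1, 1], 128)
  # identity at gamma 1 on already-quantized input
  v <- matrix(0:255 / 255, 16, 16)
  expect_equal(gammaCorrect(v, 1), round(255 * v))
  # monotonicity for several exponents
  for (g in c(0.3, 0.5, 2, 4)) {
    out <- gammaCorrect(matrix(0:255 / 255, 1, 256), g)
    expect_false(is.unsorted(as.numeric(out)))
  }
  expect_error(gammaCorrect(v, 0), "positive")
})

test_that("Otsu thresholding equals the exhaustive brute-force oracle", {
  # bimodal example: equal masses at 10 and 200
  h <- integer(256); h[10 + 1] <- 50; h[200 + 1] <- 50
  t0 <- otsuThreshold(h)
  expect_gt(t0, 10)
  expect_lte(t0, 200)
  expect_equal(as.integer(t0), otsuBruteForce(h))
  # random histograms, various shapes
  set.seed(81)
  for (i in 1:200) {
    h <- rpois(256, lambda = runif(1, 0.1, 5))
    if (sum(h) == 0 || sum(h > 0) < 2) next
    expect_equal(as.integer(otsuThreshold(h)), otsuBruteForce(h))
  }
  # degenerate single-valued image
  h1 <- integer(256); h1[7 + 1] <- 10
  t1 <- otsuThreshold(h1)
  expect_equal(as.integer(t1), 7)
  expect_true(isTRUE(attr(t1, "degenerate")))
})

test_that("grid removal keeps the curve and drops the grid", {
  src <- generateECG(nsrSpec(seed = 7), 10, 250)$signal
  img <- renderReport(src)
  layers <- reportLayers(img)
  g <- gammaCorrect(img, 0.5)
  binary <- g < otsuThreshold(tabulate(g + 1, 256))
  curve <- separateCurve(binary, layers$grid)
  pureGrid <- layers$grid & !layers$trace
  expect_lt(sum(curve & pureGrid) / sum(pureGrid), 0.01)
  # gridless image passes through unchanged
  plain <- matrix(FALSE, 20, 30); plain[10, ] <- TRUE
  expect_equal(separateCurve(plain, matrix(FALSE, 20, 30)), plain)
  # a pure-grid image nearly empties (auto-detected grid)
  gridOnly <- matrix(FALSE, 50, 50)
  gridOnly[seq(1, 50, 5), ] <- TRUE
  gridOnly[, seq(1, 50, 5)] <- TRUE
  out <- separateCurve(gridOnly)
  expect_lt(mean(out), 0.01)
})

test_that("trace extraction walks columns and repairs gaps linearly", {
  m <- matrix(FALSE, 50, 40)
  m[30, ] <- TRUE
  tc <- extractTrace(m)
  expect_true(all(tc$position == 30))
  # a 5-column gap on a sloped line is bridged on the straight line
  m2 <- matrix(FALSE, 60, 40)
  rows <- round(seq(10, 49, length.out = 40))
  for (j in 1:40) m2[rows[j], j] <- TRUE
  m2[, 18:22] <- FALSE
  tc2 <- extractTrace(m2)
  expect_true(all(tc2$breakpoints[18:22]))
  want <- approx(c(17, 23), rows[c(17, 23)], xout = 18:22)$y
  expect_equal(tc2$position[18:22], want, tolerance = 1e-9)
  # too many missing columns is a hard failure
  m3 <- matrix(FALSE, 20, 100)
  m3[10, c(1:20, 90:100)] <- TRUE
  expect_error(extractTrace(m3), "unreliable")
})

test_that("calibration maps pixels to seconds and millivolts", {
  cal <- list(px_per_mm = 4, mm_per_s = 25, mm_per_mV = 10,
              baseline_row = 100, x0 = 1)
  # baseline-constant trace -> all-zero signal
  tcFlat <- list(position = rep(100, 200), domain = c(1, 200))
  sFlat <- calibrateTrace(tcFlat, cal, fsOut = 100)
  expect_true(all(abs(samples(sFlat)) < 1e-12))
  # a 40 px deflection at 4 px/mm, 10 mm/mV reads 1.0 mV
  tcStep <- list(position = c(rep(100, 100), rep(60, 100)),
                 domain = c(1, 200))
  sStep <- calibrateTrace(tcStep, cal, fsOut = 100)
  expect_equal(max(samples(sStep)), 1.0, tolerance = 1e-9)
})

test_that("a rendered calibration pulse occupies the expected pixel box", {
  fs <- 500
  pulse <- numeric(2 * fs)                   # 2 s strip
  pulse[(0.5 * fs):(0.6 * fs - 1) + 1] <- 1  # 1 mV for 0.1 s
  img <- renderReport(ecgSignal(pulse, fs), pxPerMm = 4, mmPerS = 25,
                      mmPerMV = 10)
  tr <- reportLayers(img)$trace
  cal <- img@calibration
  # columns whose ink reaches the 1 mV level
  top <- cal$baseline_row - 40
  highCols <- which(colSums(tr[1:(top + 1), , drop = FALSE]) > 0)
  expect_lt(abs(length(highCols) - 10), 3)
  # vertical extent of the pulse above baseline
  midCol <- round(mean(highCols))
  inked <- which(tr[, midCol])
  expect_equal(cal$baseline_row - min(inked), 40, tolerance = 2)
})

test_that("column centroids of the rendered trace reproduce the input", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  src <- ecgSignal(sin(2 * pi * 1 * t), fs)   # smooth 1 Hz, +/-1 mV
  img <- renderReport(src)
  tr <- reportLayers(img)$trace
  cal <- img@calibration
  counts <- colSums(tr)
  cols <- which(counts > 0)
  centroid <- as.numeric(crossprod(seq_len(nrow(tr)), tr))[cols] / counts[cols]
  tCols <- (cols - cal$x0) / (cal$px_per_mm * cal$mm_per_s)
  keep <- tCols >= 0 & tCols <= max(t)
  wantRow <- cal$baseline_row -
    approx(t, samples(src), xout = tCols[keep])$y *
    cal$mm_per_mV * cal$px_per_mm
  rmse <- sqrt(mean((centroid[keep] - wantRow)^2))
  expect_lt(rmse, 1)
})

test_that("render-digitize round trips correlate with the source", {
  rs <- vapply(1:3, function(s) {
    src <- generateECG(nsrSpec(seed = s), 10, 250)$signal
    dig <- digitizeReport(renderReport(src))
    n <- min(length(samples(src)), length(samples(dig)))
    cor(samples(src)[1:n], samples(dig)[1:n])
  }, numeric(1))
  expect_true(all(rs >= 0.95))
})

test_that("rendering rejects strips wider than the drawing limit", {
  long <- ecgSignal(rep(0, 250 * 60), 250)
  expect_error(renderReport(long, maxWidthPx = 2000), "requires")
})

test_that("a flat signal draws a horizontal line at the baseline row", {
  img <- renderReport(ecgSignal(rep(0, 2500), 250), lineWidth = 1)
  tr <- reportLayers(img)$trace
  rowsInked <- which(rowSums(tr) > 0)
  expect_equal(rowsInked, img@calibration$baseline_row)
})

test_that("PNG write/read round trips the pixel raster", {
  src <- generateECG(nsrSpec(seed = 8), 10, 250)$signal
  img <- renderReport(src)
  path <- withr::local_tempfile(fileext = ".png")
  writeReportPNG(img, path)
  back <- readReportPNG(path, calibration = img@calibration)
  expect_equal(dim(back@pixels), dim(img@pixels))
  expect_lt(max(abs(back@pixels - img@pixels)), 1 / 255)
  dig1 <- digitizeReport(img); dig2 <- digitizeReport(back)
  expect_gt(cor(samples(dig1), samples(dig2)), 0.999)
})
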