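# hand-built models exercise the decision function without training
stubModel <- function(sv, coefs, bias, gamma = 1, classes = c("pos", "neg"),
                      features = colnames(sv)) {
  new("SVMFit", supportVectors = sv, dualCoefs = coefs, bias = bias,
      gamma = gamma, cost = Inf,
      scaler = list(center = setNames(rep(0, ncol(sv)), features),
                    spread = setNames(rep(1, ncol(sv)), features),
                    features = features),
      classes = classes, features = features)
}

test_that("the kernel decision function matches direct summation", {
  sv <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- stubModel(sv, coefs = 1, bias = 0)
  d <- svmDecide(m, data.frame(f1 = 0, f2 = 0))
  expect_equal(d$score, 1)                  # exp(0) = 1
  expect_equal(d$label, "pos")

  # two symmetric SVs with opposite signs, equidistant query: tie -> positive
  sv2 <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("f1", "f2")))
  m2 <- stubModel(sv2, coefs = c(1, -1), bias = 0)
  d2 <- svmDecide(m2, data.frame(f1 = 0, f2 = 5))
  expect_equal(d2$score, 0)
  expect_equal(d2$label, "pos")

  # 3-SV model vs brute-force evaluation to 1e-12
  set.seed(41)
  sv3 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  co <- c(0.7, -1.2, 0.5); b <- 0.3; g <- 0.8
  m3 <- stubModel(sv3, co, b, gamma = g)
  xq <- data.frame(f1 = rnorm(10), f2 = rnorm(10))
  got <- svmDecide(m3, xq)$score
  want <- vapply(seq_len(10), function(i) {
    s <- 0
    for (j in 1:3)
      s <- s + co[j] * exp(-g * sum((sv3[j, ] - c(xq$f1[i], xq$f2[i]))^2))
    s + b
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("training separable blobs reaches perfect training accuracy", {
  bl <- makeBlobs(n = 30, sep = 6, sd = 0.5, seed = 42)
  fit <- svmTrain(bl$x, bl$y, cost = 10, gamma = 1)
  pred <- svmDecide(fit, bl$x)
  expect_equal(mean(pred$label == bl$y), 1)
  expect_true(all(abs(fit@dualCoefs) <= fit@cost + 1e-8))
  # decision agrees with the backend's own predictions
  xs <- as.matrix(applyScaler(fit@scaler, bl$x)[, fit@features])
  backend <- e1071::svm(xs, factor(bl$y, levels = fit@classes),
                        type = "C-classification", kernel = "radial",
                        cost = 10, gamma = 1, scale = FALSE)
  expect_equal(pred$label, as.character(predict(backend, xs)))
})

test_that("the RBF kernel solves the XOR pattern a linear machine cannot", {
  withr::with_seed(43, {
    n <- 30
    x <- data.frame(
      f1 = c(rnorm(n, -1, 0.2), rnorm(n, 1, 0.2),
             rnorm(n, -1, 0.2), rnorm(n, 1, 0.2)),
      f2 = c(rnorm(n, -1, 0.2), rnorm(n, 1, 0.2),
             rnorm(n, 1, 0.2), rnorm(n, -1, 0.2)))
    y <- rep(c("same", "same", "diff", "diff"), each = n)
  })
  fit <- svmTrain(x, y, cost = 10, gamma = 1)
  expect_gt(mean(svmDecide(fit, x)$label == y), 0.90)
})

test_that("conflicting duplicate points drive dual coefficients to the C bound", {
  x <- data.frame(f1 = c(0, 0, 1, 1), f2 = c(0, 0, 1, 1))
  y <- c("a", "b", "a", "b")
  expect_silent(fit <- svmTrain(x, y, cost = 5, gamma = 1))
  expect_true(any(abs(abs(fit@dualCoefs) - 5) < 1e-6))
})

test_that("single-class input is rejected", {
  expect_error(svmTrain(data.frame(a = 1:5), rep("x", 5), 1, 1),
               "two classes")
})

test_that("cross-validated fitness behaves across the separability range", {
  bl <- makeBlobs(n = 30, sep = 8, sd = 0.5, seed = 44)
  expect_equal(cvFitness(bl$x, bl$y, 10, 1, kFolds = 3, seed = 1), 1.0)
  # permutation null on balanced data sits near chance
  ySh <- withr::with_seed(45, sample(bl$y))
  fSh <- cvFitness(bl$x, ySh, 10, 1, kFolds = 3, seed = 1)
  expect_lt(abs(fSh - 0.5), 0.1)
  # fold assignment is seed-stable
  expect_identical(cvFitness(bl$x, bl$y, 2, 0.5, 3, seed = 7),
                   cvFitness(bl$x, bl$y, 2, 0.5, 3, seed = 7))
  expect_warning(cvFitness(bl$x[c(1:2, 31:60), ], bl$y[c(1:2, 31:60)],
                           1, 1, kFolds = 5, seed = 1),
                 "reducing folds")
})

test_that("models survive a JSON round trip bit-for-bit in behaviour", {
  bl <- makeBlobs(n = 20, sep = 4, seed = 46)
  fit <- svmTrain(bl$x, bl$y, cost = 3, gamma = 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(fit, path)
  back <- readModelJSON(path)
  expect_equal(svmDecide(back, bl$x)$score, svmDecide(fit, bl$x)$score,
               tolerance = 1e-12)
})
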