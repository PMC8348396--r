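test_that("the contraction-expansion schedule decays linearly", {
  expect_equal(lambdaSchedule(0, 30, 1, 0.5), 1)
  expect_equal(lambdaSchedule(30, 30, 1, 0.5), 0.5)
  expect_equal(lambdaSchedule(15, 30, 1, 0.5), 0.75)
  expect_error(lambdaSchedule(31, 30), "must lie")
})

test_that("the position update reproduces the hand-worked example", {
  # phi = 0.5, pbest = 2, gbest = 4 -> attractor p = 3; x = 1, Mbest = 5,
  # lambda = 0.75, u = e^-1 so ln(1/u) = 1, k = 0.7 -> 3 + 0.75*4*1 = 6
  expect_equal(qpsoUpdate(1, 2, 4, 5, 0.75, exp(-1), 0.7, 0.5), 6)
  # contraction limits collapse onto the attractor
  expect_equal(qpsoUpdate(1, 2, 4, 5, 0, 0.3, 0.7, 0.5), 3)
  expect_equal(qpsoUpdate(1, 2, 4, 5, 0.75, 1, 0.7, 0.5), 3)
  # k below one half flips the sign of the step
  expect_equal(qpsoUpdate(1, 2, 4, 5, 0.75, exp(-1), 0.2, 0.5), 0)
  expect_error(qpsoUpdate(1, 2, 4, 5, 0.75, 0, 0.7, 0.5), "0, 1")
})

test_that("the update equals an independent restatement on 1000 random tuples", {
  set.seed(51)
  for (i in 1:1000) {
    x <- runif(1, -10, 10); pb <- runif(1, -10, 10)
    gb <- runif(1, -10, 10); mb <- runif(1, -10, 10)
    lam <- runif(1, 0, 1.5); u <- runif(1, 1e-6, 1)
    k <- runif(1); phi <- runif(1)
    expect_equal(qpsoUpdate(x, pb, gb, mb, lam, u, k, phi),
                 qpsoOracle(x, pb, gb, mb, lam, u, k, phi),
                 tolerance = 1e-12)
  }
})

test_that("bounds clamp out-of-range moves", {
  b <- rbind(-1, 1)
  got <- qpsoUpdate(0.5, 0.9, 0.9, 5, 1, exp(-2), 0.9, 0.5, bounds = b)
  expect_lte(got, 1)
  expect_gte(got, -1)
})

test_that("the swarm collapses onto a known 1-D optimum across seeds", {
  finals <- vapply(1:10, function(s)
    abs(iqpsoOptimize(bounds = rbind(-10, 10),
                      fitness = function(p) -p[1]^2,
                      nParticles = 20, tMax = 30, seed = s)$position[1]),
    numeric(1))
  expect_true(all(finals < 0.01))
})

test_that("global-best fitness history is non-decreasing and seeded runs repeat", {
  r1 <- iqpsoOptimize(bounds = rbind(-5, 5),
                      fitness = function(p) -abs(p[1] - 2),
                      nParticles = 10, tMax = 15, seed = 3)
  expect_false(is.unsorted(r1$history$fitness))
  r2 <- iqpsoOptimize(bounds = rbind(-5, 5),
                      fitness = function(p) -abs(p[1] - 2),
                      nParticles = 10, tMax = 15, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$evaluations, 150)
})

test_that("early stopping engages on a flat fitness plateau", {
  r <- iqpsoOptimize(bounds = rbind(-5, 5), fitness = function(p) 1,
                     nParticles = 5, tMax = 50, seed = 2, patience = 4)
  expect_lt(nrow(r$history), 50)
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  # surrogate objective with a unique optimum; the grid must find the
  # closest grid point
  f <- function(cst, gam) -((log10(cst) - 1)^2 + (log10(gam) + 1)^2)
  bl <- makeBlobs(n = 15, sep = 6, sd = 0.4, seed = 52)
  g1 <- gridSearchSVM(bl$x, bl$y, cRange = 7, gammaRange = 0.3,
                      kFolds = 2, seed = 1)
  expect_equal(g1$cost, 7)
  expect_equal(g1$gamma, 0.3)
  expect_equal(dim(g1$surface), c(1, 1))
  g2 <- gridSearchSVM(bl$x, bl$y, cRange = c(1, 10, 100),
                      gammaRange = c(0.01, 0.1, 1, 10), kFolds = 2,
                      seed = 1)
  expect_equal(dim(g2$surface), c(3, 4))
  expect_equal(g2$evaluations, 12)
  # ties break toward the smallest C then gamma: a perfectly separable
  # problem scores 1.0 everywhere reasonable
  blEasy <- makeBlobs(n = 20, sep = 10, sd = 0.3, seed = 53)
  g3 <- gridSearchSVM(blEasy$x, blEasy$y, cRange = c(1, 10),
                      gammaRange = c(0.1, 1), kFolds = 2, seed = 1)
  expect_equal(g3$fitness, 1)
  expect_equal(g3$cost, 1)
  expect_equal(g3$gamma, 0.1)
  expect_error(gridSearchSVM(bl$x, bl$y, numeric(0), 1), "nonempty")
})

test_that("swarm and grid agree on an easy tuning landscape", {
  bl <- makeBlobs(n = 30, sep = 4, seed = 54)
  gr <- gridSearchSVM(bl$x, bl$y, cRange = 10^seq(-1, 3),
                      gammaRange = 10^seq(-2, 1), kFolds = 3, seed = 6)
  iq <- iqpsoOptimize(bl$x, bl$y, nParticles = 10, tMax = 10,
                      kFolds = 3, seed = 6)
  expect_gte(iq$fitness, gr$fitness - 0.05)
})
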