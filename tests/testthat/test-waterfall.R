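# build a trivial stage stub that always answers `answer`
stageStub <- function(classes, answer, features) {
  sv <- matrix(0, 1, length(features),
               dimnames = list(NULL, features))
  bias <- if (answer == classes[1]) 1 else -1
  new("SVMFit", supportVectors = sv, dualCoefs = 0, bias = bias,
      gamma = 1, cost = Inf,
      scaler = list(center = setNames(rep(0, length(features)), features),
                    spread = setNames(rep(1, length(features)), features),
                    features = features),
      classes = classes, features = features)
}

stubHybrid <- function(diagAnswer, predAnswer) {
  cols <- featureColumns()
  new("HybridModel",
      diagnosis = stageStub(c("AF", "N"), diagAnswer, cols$diagnosis),
      prediction = stageStub(c("PAF", "N"), predAnswer, cols$prediction),
      imputeMeans = setNames(rep(0, length(cols$prediction)),
                             cols$prediction))
}

fakeFeatures <- function(n, label = NA_character_) {
  cols <- featureColumns()$all
  df <- as.data.frame(matrix(runif(n * length(cols)), n,
                             dimnames = list(NULL, cols)))
  df$label <- label
  df
}

test_that("window labeling follows the any-AF-overlap rule", {
  ann <- data.frame(sample = c(0, 1000, 5000),
                    rhythm = c("(N", "(AFIB", "(N"))
  expect_equal(labelSegmentAF(ann, 0, 999), "N")
  expect_equal(labelSegmentAF(ann, 999, 1001), "AF")
  expect_equal(labelSegmentAF(ann, 4000, 6000), "AF")
  expect_equal(labelSegmentAF(ann, 5000, 8000), "N")
  # an AF run starting at the window's last sample still counts
  ann2 <- data.frame(sample = c(0, 2999), rhythm = c("(N", "(AFIB"))
  expect_equal(labelSegmentAF(ann2, 0, 3000), "AF")
  expect_equal(labelSegmentAF(data.frame(sample = 0, rhythm = "(N"),
                              0, 3000), "N")
})

test_that("window labels equal a brute-force per-sample rhythm scan", {
  withr::with_seed(61, {
    nAnn <- 12
    recordEnd <- 30L * 1000L
    ann <- data.frame(
      sample = sort(sample(0:(recordEnd - 1), nAnn)),
      rhythm = sample(c("(N", "(AFIB", "(AFL"), nAnn, replace = TRUE))
    ann$sample[1] <- 0
  })
  # oracle: expand the rhythm to every sample, then scan each window
  perSample <- character(recordEnd)
  for (i in seq_len(nrow(ann))) {
    to <- if (i < nrow(ann)) ann$sample[i + 1] else recordEnd
    if (to > ann$sample[i])
      perSample[(ann$sample[i] + 1):to] <- ann$rhythm[i]
  }
  for (w in 0:29) {
    lo <- w * 1000L; hi <- lo + 1000L
    want <- if (any(perSample[(lo + 1):hi] == "(AFIB")) "AF" else "N"
    expect_equal(labelSegmentAF(ann, lo, hi, recordEnd), want,
                 info = paste("window", w))
  }
})

test_that("stage stubs compose exactly as the waterfall dictates", {
  withr::with_seed(62, feats <- fakeFeatures(25))
  allAF <- predictHybrid(stubHybrid("AF", "PAF"), feats)
  expect_true(all(allAF$label == "AF"))
  expect_true(all(allAF$stage == 1))
  expect_true(all(is.na(allAF$score2)))       # stage 2 never invoked

  allPAF <- predictHybrid(stubHybrid("N", "PAF"), feats)
  expect_true(all(allPAF$label == "PAF"))
  expect_true(all(allPAF$stage == 2))

  allN <- predictHybrid(stubHybrid("N", "N"), feats)
  expect_true(all(allN$label == "N"))
})

test_that("training requires every class and excludes AF from stage 2", {
  withr::with_seed(63, {
    feats <- rbind(fakeFeatures(10, "N"), fakeFeatures(10, "AF"),
                   fakeFeatures(10, "PAF"))
  })
  expect_error(trainHybrid(feats[feats$label != "PAF", ]), "PAF")
  # AF rows with missing P features must not break stage-2 training,
  # because stage 2 never sees them
  feats2 <- feats
  feats2[feats2$label == "AF",
         c("pr", "pamp", "ca1", "ca2", "ca3", "cd1", "cd2", "cd3")] <- NA
  hm <- trainHybrid(feats2)
  expect_s4_class(hm, "HybridModel")
  expect_setequal(hm@prediction@classes, c("PAF", "N"))
  expect_setequal(hm@diagnosis@classes, c("AF", "N"))
  expect_true(all(is.finite(hm@imputeMeans)))
})

test_that("seeded training twice writes identical model files", {
  withr::with_seed(64, {
    feats <- rbind(fakeFeatures(12, "N"), fakeFeatures(12, "AF"),
                   fakeFeatures(12, "PAF"))
  })
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(trainHybrid(feats), p1)
  writeModelJSON(trainHybrid(feats), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("hybrid predictions conserve segments and compose the stages", {
  ds <- fxGet("segments_small", function()
    makeSegmentDataset(nPerClass = 12, segSeconds = 60, seed = 77))
  withr::with_seed(65, {
    idx <- unlist(lapply(c("N", "AF", "PAF"), function(cl)
      sample(which(ds$label == cl), 6)))
  })
  train <- ds[idx, ]; test <- ds[-idx, ]
  hm <- suppressWarnings(trainHybrid(train))
  pred <- suppressWarnings(predictHybrid(hm, test))
  # conservation: exactly one label from the vocabulary per segment
  expect_equal(nrow(pred), nrow(test))
  expect_true(all(pred$label %in% c("N", "AF", "PAF")))
  # compositional bookkeeping oracle: recompute both stages directly
  s1 <- svmDecide(hm@diagnosis, test)
  expected <- s1$label
  idx2 <- which(expected == "N")
  x2 <- test[idx2, hm@prediction@features]
  for (f in names(x2)) x2[[f]][is.na(x2[[f]])] <- hm@imputeMeans[[f]]
  expected[idx2] <- svmDecide(hm@prediction, x2)$label
  expect_equal(pred$label, expected)
  # AF can only come from stage 1, PAF only from stage 2
  expect_true(all(pred$stage[pred$label == "AF"] == 1))
  expect_true(all(pred$stage[pred$label == "PAF"] == 2))
  # the hybrid's AF row equals stage 1's AF row
  cmH <- buildConfusion(test$label, pred$label, c("N", "PAF", "AF"))
  s1af <- s1$label[test$label == "AF"]
  expect_equal(unname(cmH["AF", "AF"]), sum(s1af == "AF"))
  expect_equal(sum(cmH["AF", c("N", "PAF")]), sum(s1af == "N"))
})
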