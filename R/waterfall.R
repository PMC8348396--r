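#' Label a 5-minute window from a rhythm annotation stream
#'
#' Implements the segment-labeling rule used for long-term AF records:
#' a window is labeled AF as soon as any AF rhythm annotation overlaps
#' it, otherwise N. Rhythm annotations mark onsets: each annotation's
#' rhythm holds from its sample until the next annotation (or the end
#' of the record).
#'
#' @param ann data.frame with columns \code{sample} (0-based onset
#'   index) and \code{rhythm} (e.g. \code{"(AFIB"}, \code{"(N"};
#'   anything containing \code{"AFIB"} counts as AF).
#' @param windowStart,windowEnd window bounds in samples, half-open
#'   \code{[start, end)}.
#' @param recordEnd total record length in samples (close of the last
#'   rhythm run).
#' @return \code{"AF"} or \code{"N"}.
#' @export
labelSegmentAF <- function(ann, windowStart, windowEnd,
                           recordEnd = Inf) {
  stopIfNot(windowEnd > windowStart, "empty window")
  if (nrow(ann) == 0L) return("N")
  ord <- order(ann$sample)
  starts <- ann$sample[ord]
  ends <- c(starts[-1], recordEnd)
  isAF <- grepl("AFIB", ann$rhythm[ord], fixed = TRUE)
  overlap <- starts < windowEnd & ends > windowStart
  if (any(isAF & overlap)) "AF" else "N"
}

#' Train the two-stage waterfall hybrid model
#'
#' Stage 1 (diagnosis, AF vs N) is trained on all segments using the
#' six RR features, with PAF-precursor segments treated as N (they are
#' sinus rhythm, not AF onset; set \code{pafAsN = FALSE} to exclude
#' them instead). Stage 2 (prediction, PAF vs N) is trained on the
#' non-AF segments only, using all 14 features; missing P-dependent
#' features there are imputed with the stage-2 training means, which
#' are stored for reuse at prediction time.
#'
#' @param featTable data.frame of segment features (see
#'   [segmentFeatures()]) with a \code{label} column covering all of
#'   \code{"N"}, \code{"AF"}, \code{"PAF"}.
#' @param costDiag,gammaDiag,costPred,gammaPred hyperparameters of the
#'   two stages.
#' @param pafAsN treat PAF segments as N when training stage 1.
#' @return A [HybridModel-class].
#' @export
trainHybrid <- function(featTable, costDiag = 10, gammaDiag = 0.1,
                        costPred = 10, gammaPred = 0.1, pafAsN = TRUE) {
  featTable <- as.data.frame(featTable)
  for (cl in c("N", "AF", "PAF"))
    if (!any(featTable$label == cl))
      stop("class absent from training data: ", cl, call. = FALSE)
  cols <- featureColumns()

  stage1 <- if (pafAsN) featTable else featTable[featTable$label != "PAF", ]
  y1 <- ifelse(stage1$label == "AF", "AF", "N")
  diag <- svmTrain(stage1[, cols$diagnosis], y1, cost = costDiag,
                   gamma = gammaDiag, positive = "AF")

  stage2 <- featTable[featTable$label != "AF", ]
  x2 <- stage2[, cols$prediction]
  imputeMeans <- vapply(x2, function(col) mean(col, na.rm = TRUE),
                        numeric(1))
  for (f in names(x2))
    x2[[f]][is.na(x2[[f]])] <- imputeMeans[[f]]
  pred <- svmTrain(x2, stage2$label, cost = costPred, gamma = gammaPred,
                   positive = "PAF")
  new("HybridModel", diagnosis = diag, prediction = pred,
      imputeMeans = imputeMeans)
}

#' Predict segment labels with the waterfall ensemble
#'
#' Every segment passes through stage 1; segments called AF are final
#' (stage 2 never sees them), the rest go to stage 2 which splits them
#' into PAF and N. Missing P-dependent features at stage 2 (typical
#' when no P wave was delineated) are imputed with the stage-2 training
#' means, with a warning.
#'
#' @param model a [HybridModel-class].
#' @param featTable data.frame of segment feature rows.
#' @return data.frame with one row per segment: \code{label} (N, AF or
#'   PAF), \code{stage} (1 or 2, which stage decided), \code{score1},
#'   \code{score2} (signed decision values; \code{score2} is \code{NA}
#'   for stage-1 decisions).
#' @export
predictHybrid <- function(model, featTable) {
  stopIfNot(is(model, "HybridModel"), "'model' must be a HybridModel")
  featTable <- as.data.frame(featTable)
  n <- nrow(featTable)
  s1 <- svmDecide(model@diagnosis, featTable)
  out <- data.frame(label = s1$label, stage = 1L,
                    score1 = s1$score, score2 = NA_real_)
  toStage2 <- which(s1$label == "N")
  if (length(toStage2)) {
    x2 <- featTable[toStage2, model@prediction@features, drop = FALSE]
    nMiss <- sum(is.na(as.matrix(x2)))
    if (nMiss > 0) {
      warning(sprintf(
        "imputing %d missing stage-2 feature value(s) with training means",
        nMiss))
      for (f in names(x2))
        x2[[f]][is.na(x2[[f]])] <- model@imputeMeans[[f]]
    }
    s2 <- svmDecide(model@prediction, x2)
    out$label[toStage2] <- s2$label
    out$stage[toStage2] <- 2L
    out$score2[toStage2] <- s2$score
  }
  out
}
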