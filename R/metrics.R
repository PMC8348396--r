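#' Build a confusion matrix
#'
#' Rows are the actual classes, columns the predicted classes (the
#' convention of clinical classification tables).
#'
#' @param actual,predicted equal-length label vectors; every value must
#'   appear in \code{classes}.
#' @param classes ordered class vocabulary.
#' @return An integer matrix \code{counts[actual, predicted]} with
#'   dimnames \code{actual}/\code{predicted}.
#' @examples
#' buildConfusion(c("a", "b", "a"), c("a", "b", "b"), c("a", "b"))
#' @export
buildConfusion <- function(actual, predicted, classes) {
  stopIfNot(length(actual) == length(predicted),
            "'actual' and 'predicted' must have equal length")
  stopIfNot(length(actual) > 0, "empty input")
  stopIfNot(all(c(actual, predicted) %in% classes),
            "labels outside the class vocabulary")
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

#' Sensitivity, specificity and accuracy of a 2x2 confusion matrix
#'
#' With the positive class in the stated row/column:
#' \deqn{SE = TP/(TP+FN), \quad SP = TN/(TN+FP), \quad
#'   Acc = (TP+TN)/(TP+TN+FP+FN).}
#' A zero denominator yields \code{NA} for that metric.
#'
#' @param cm 2x2 matrix, rows actual, columns predicted.
#' @param positive positive class name (must match a dimname), or the
#'   row/column index when the matrix is unnamed.
#' @return Named numeric: \code{se}, \code{sp}, \code{acc} (fractions
#'   in \code{[0, 1]}).
#' @examples
#' cm <- matrix(c(357, 3, 3, 357), 2, byrow = TRUE,
#'              dimnames = list(actual = c("AF", "N"),
#'                              predicted = c("AF", "N")))
#' binaryMetrics(cm, "AF")
#' @export
binaryMetrics <- function(cm, positive = 1) {
  cm <- as.matrix(cm)
  stopIfNot(all(dim(cm) == c(2, 2)), "'cm' must be 2x2")
  if (is.character(positive)) {
    stopIfNot(positive %in% rownames(cm),
              "'positive' not found among the classes")
    pi <- match(positive, rownames(cm))
  } else pi <- positive
  ni <- 3 - pi
  tp <- cm[pi, pi]; fn <- cm[pi, ni]
  fp <- cm[ni, pi]; tn <- cm[ni, ni]
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(se = rat(tp, tp + fn), sp = rat(tn, tn + fp),
    acc = rat(tp + tn, tp + tn + fp + fn))
}

#' Collapse a 3x3 confusion matrix to one-vs-rest 2x2
#'
#' For the chosen class c: \code{TP} = the diagonal cell of c,
#' \code{FN} = the rest of c's actual row, \code{FP} = the rest of c's
#' predicted column, \code{TN} = everything else (all cells with
#' neither actual nor predicted equal to c — including off-diagonal
#' confusions among the other classes).
#'
#' @param cm3 square confusion matrix (rows actual, columns predicted).
#' @param class the positive class name or index.
#' @return 2x2 matrix with classes \code{c(class, "rest")}.
#' @export
collapseOvr <- function(cm3, class) {
  cm3 <- as.matrix(cm3)
  stopIfNot(nrow(cm3) == ncol(cm3), "'cm3' must be square")
  ci <- if (is.character(class)) match(class, rownames(cm3)) else class
  stopIfNot(!is.na(ci) && ci >= 1 && ci <= nrow(cm3),
            "'class' not found")
  tp <- cm3[ci, ci]
  fn <- sum(cm3[ci, -ci])
  fp <- sum(cm3[-ci, ci])
  tn <- sum(cm3[-ci, -ci])
  lab <- if (is.character(class)) class else rownames(cm3)[ci]
  if (is.null(lab)) lab <- "positive"
  matrix(c(tp, fn, fp, tn), 2, byrow = TRUE,
         dimnames = list(actual = c(lab, "rest"),
                         predicted = c(lab, "rest")))
}

#' One-vs-rest metrics for a multi-class confusion matrix
#'
#' Sensitivity, specificity and accuracy of one class against the
#' rest, per the one-vs-rest collapsing of [collapseOvr()].
#'
#' @param cm3 square confusion matrix (rows actual, columns predicted).
#' @param class the positive class.
#' @return Named numeric: \code{se}, \code{sp}, \code{acc}.
#' @examples
#' cm <- matrix(c(35, 5, 0, 2, 37, 1, 0, 1, 39), 3, byrow = TRUE,
#'              dimnames = list(actual = c("N", "PAF", "AF"),
#'                              predicted = c("N", "PAF", "AF")))
#' ovrMetrics(cm, "AF")
#' @export
ovrMetrics <- function(cm3, class) {
  binaryMetrics(collapseOvr(cm3, class), 1)
}

#' Micro-averaged (overall) accuracy
#'
#' @param cm square confusion matrix.
#' @return trace / total.
#' @export
overallAccuracy <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm)
}

#' Format a metric as a percentage the way clinical tables print it
#'
#' Rounds half-up to one decimal (so 0.98750 prints as "98.8").
#'
#' @param x fraction in \code{[0, 1]}.
#' @param digits decimals to keep.
#' @return Numeric percentage (not a string).
#' @export
asPercent <- function(x, digits = 1) {
  floor(x * 100 * 10^digits + 0.5) / 10^digits
}
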