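#' Train a soft-margin RBF support vector machine
#'
#' Thin wrapper around the libsvm quadratic-programming solver
#' (\code{e1071::svm}) that freezes a z-score scaler on the training
#' rows, fits the C-classification dual with an RBF kernel, and stores
#' the solution in an explicit [SVMFit-class] (support vectors, dual
#' coefficients \eqn{\alpha_i^* y_i}, bias \eqn{b^*}) so the decision
#' function can be evaluated transparently by [svmDecide()].
#'
#' @param x data.frame or matrix of feature rows (unscaled).
#' @param y class labels, exactly two distinct values.
#' @param cost regularization constant C.
#' @param gamma RBF kernel width.
#' @param positive which label maps to +1; default the first of
#'   \code{sort(unique(y))}.
#' @param features columns of \code{x} to use (default all numeric).
#' @return An [SVMFit-class].
#' @examples
#' set.seed(1)
#' x <- data.frame(a = c(rnorm(20, -2), rnorm(20, 2)), b = rnorm(40))
#' fit <- svmTrain(x, rep(c("neg", "pos"), each = 20), cost = 10, gamma = 1)
#' fit
#' @export
svmTrain <- function(x, y, cost = 1, gamma = 1, positive = NULL,
                     features = NULL) {
  x <- as.data.frame(x)
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) != 2L)
    stop("exactly two classes required, got: ",
         paste(cls, collapse = ", "), call. = FALSE)
  if (is.null(positive)) positive <- cls[1]
  stopIfNot(positive %in% cls, "'positive' must be one of the labels")
  classes <- c(positive, setdiff(cls, positive))
  if (is.null(features))
    features <- names(x)[vapply(x, is.numeric, logical(1))]
  scaler <- fitScaler(x, features)
  xs <- as.matrix(applyScaler(scaler, x)[, features, drop = FALSE])
  yf <- factor(y, levels = classes)      # first level -> +1 in libsvm
  fit <- e1071::svm(xs, yf, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  # libsvm orients decision values toward the class it saw first
  # (fit$labels[1]); flip so that positive scores mean classes[1]
  flip <- if (levels(yf)[fit$labels[1]] == classes[1]) 1 else -1
  new("SVMFit",
      supportVectors = as.matrix(fit$SV),
      dualCoefs = flip * as.numeric(fit$coefs),
      bias = flip * -fit$rho,
      gamma = gamma, cost = cost, scaler = scaler,
      classes = classes, features = features)
}

#' Evaluate the RBF-SVM decision function
#'
#' Computes \eqn{s(x) = \sum_i \alpha_i^* y_i \exp(-\gamma \|x_i -
#' x\|^2) + b^*} by direct summation over the stored support vectors
#' and returns \code{sign(s)} mapped to the class labels (a tie,
#' \eqn{s = 0}, goes to the positive class).
#'
#' @param model an [SVMFit-class].
#' @param x a data.frame/matrix of unscaled feature rows, or a single
#'   named numeric vector. Set \code{scaled = TRUE} if \code{x} is
#'   already on the model's scaled feature scale.
#' @param scaled whether \code{x} is already scaled.
#' @return data.frame with columns \code{label} and \code{score}.
#' @export
svmDecide <- function(model, x, scaled = FALSE) {
  stopIfNot(is(model, "SVMFit"), "'model' must be an SVMFit")
  if (is.numeric(x) && is.null(dim(x)))
    x <- as.data.frame(as.list(x))
  x <- as.data.frame(x)
  missing <- setdiff(model@features, names(x))
  if (length(missing))
    stop("input lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!scaled) x <- applyScaler(model@scaler, x)
  xm <- as.matrix(x[, model@features, drop = FALSE])
  sv <- model@supportVectors
  scores <- vapply(seq_len(nrow(xm)), function(i) {
    d2 <- rowSums((sv - matrix(xm[i, ], nrow(sv), ncol(sv),
                               byrow = TRUE))^2)
    sum(model@dualCoefs * exp(-model@gamma * d2)) + model@bias
  }, numeric(1))
  data.frame(label = ifelse(scores >= 0, model@classes[1],
                            model@classes[2]),
             score = scores)
}

#' Stratified k-fold cross-validated accuracy of an RBF-SVM
#'
#' The fitness function driving both tuners: folds are stratified by
#' class and fixed by \code{seed}; within each split the scaler and the
#' SVM are fit on the training folds only (via [svmTrain()]) and
#' accuracy is measured on the held-out fold. When a class has fewer
#' members than \code{kFolds}, the fold count is reduced with a
#' warning.
#'
#' @param x feature rows.
#' @param y labels (two classes).
#' @param cost,gamma SVM hyperparameters.
#' @param kFolds number of folds (at least 2).
#' @param seed integer; fixes the fold assignment.
#' @return Mean held-out accuracy across folds.
#' @export
cvFitness <- function(x, y, cost, gamma, kFolds = 3, seed = 1L) {
  x <- as.data.frame(x)
  y <- as.character(y)
  stopIfNot(kFolds >= 2, "'kFolds' must be at least 2")
  minClass <- min(table(y))
  if (minClass < kFolds) {
    warning(sprintf("smallest class has %d members; reducing folds to %d",
                    minClass, max(2, minClass)))
    kFolds <- max(2, minClass)
  }
  folds <- withLocalSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(kFolds), length(idx))
    }
    fold
  })
  accs <- vapply(seq_len(kFolds), function(k) {
    tr <- folds != k
    fit <- svmTrain(x[tr, , drop = FALSE], y[tr], cost = cost,
                    gamma = gamma)
    pred <- svmDecide(fit, x[!tr, , drop = FALSE])$label
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}
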