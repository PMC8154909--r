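# Evaluation statistics: MAE, RMSE, ZeroR baseline, bias-subtracted MAE,
# Pearson correlation, accuracy/AUC.

checkPaired <- function(predicted, actual) {
  if (length(predicted) == 0L || length(actual) == 0L)
    stop("empty input")
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (any(!is.finite(predicted)) || any(!is.finite(actual)))
    stop("non-finite values")
  invisible(TRUE)
}

#' Mean absolute error
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return mean of |predicted - actual|.
#' @export
#' @examples
#' mae(c(1, 2), c(2, 4)) # 1.5
mae <- function(predicted, actual) {
  checkPaired(predicted, actual)
  mean(abs(predicted - actual))
}

#' Root-mean-squared error
#'
#' More sensitive to outliers than [mae()]; always `>= mae` by Jensen's
#' inequality.
#'
#' @inheritParams mae
#' @return sqrt of the mean squared difference.
#' @export
rmse <- function(predicted, actual) {
  checkPaired(predicted, actual)
  sqrt(mean((predicted - actual)^2))
}

#' ZeroR baseline errors
#'
#' The ZeroR estimator constantly guesses the population mean of the label;
#' a model that does not beat ZeroR has learned nothing beyond that mean.
#' Its RMSE equals the uncorrected (population) standard deviation of the
#' labels.
#'
#' @param actual numeric label vector.
#' @return named numeric: `mae` and `rmse` of the constant-mean predictor.
#' @export
zeroR <- function(actual) {
  if (length(actual) == 0L) stop("empty input")
  m <- mean(actual)
  c(mae = mean(abs(actual - m)), rmse = sqrt(mean((actual - m)^2)))
}

#' Bias-subtracted mean absolute error (MAE*)
#'
#' Removes a rater's systematic offset before scoring, so that a consistent
#' tendency to measure long or short does not count as error. The bias is
#' `mean(actual - predicted)` and is added to the predictions before the
#' MAE is taken; predictions shifted by any constant therefore give
#' MAE* = 0 against their own base truth.
#'
#' @inheritParams mae
#' @return named numeric: `bias` and `maeStar`.
#' @export
biasSubtractedMae <- function(predicted, actual) {
  checkPaired(predicted, actual)
  bias <- mean(actual - predicted)
  c(bias = bias, maeStar = mean(abs(predicted + bias - actual)))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, length >= 2, both with non-zero variance.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  checkPaired(x, y)
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Threshold accuracy and rank-based AUC for a binary task
#'
#' Accuracy uses a 0.5 probability threshold. The AUC is the Mann-Whitney
#' statistic computed from ranks, with ties given half credit, so constant
#' probabilities yield AUC 0.5.
#'
#' @param prob predicted probabilities in [0, 1].
#' @param label binary 0/1 labels (both classes must be present for AUC).
#' @return named numeric: `accuracy` and `auc`.
#' @export
classificationMetrics <- function(prob, label) {
  checkPaired(prob, label)
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(label %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined with a single class")
  acc <- mean((prob >= 0.5) == (label == 1))
  r <- rank(prob, ties.method = "average")
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = acc, auc = auc)
}

#' Evaluation report for a set of per-fold results
#'
#' Aggregates per-fold regression or classification metrics into the
#' standard report layout: per-task mean +/- SD (SD with the n-1
#' denominator) next to the ZeroR baseline.
#'
#' @param task task name.
#' @param foldMetrics data.frame with one row per fold; columns `mae` and
#'   `rmse` (regression) or `accuracy` and `auc` (classification).
#' @param actual all validation labels, used for the ZeroR baseline
#'   (regression only).
#' @return one-row data.frame.
#' @export
evalReportRow <- function(task, foldMetrics, actual = NULL) {
  sdv <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  if ("mae" %in% names(foldMetrics)) {
    zr <- if (!is.null(actual)) zeroR(actual) else c(mae = NA_real_, rmse = NA_real_)
    data.frame(task = task, n = nrow(foldMetrics),
               mae = mean(foldMetrics$mae), maeSd = sdv(foldMetrics$mae),
               rmse = mean(foldMetrics$rmse), rmseSd = sdv(foldMetrics$rmse),
               zeroRMae = unname(zr["mae"]), zeroRRmse = unname(zr["rmse"]))
  } else {
    data.frame(task = task, n = nrow(foldMetrics),
               accuracy = mean(foldMetrics$accuracy),
               accuracySd = sdv(foldMetrics$accuracy),
               auc = mean(foldMetrics$auc))
  }
}
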