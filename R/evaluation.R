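#' Confusion-matrix metrics for lesion classification
#'
#' Melanoma — the second level of the label factor — is the positive class.
#' Sensitivity = TP/(TP+FN), precision = TP/(TP+FP), accuracy = (TP+TN)/n,
#' Dice = 2TP/(2TP+FP+FN). AUC is the Mann-Whitney rank statistic over the
#' continuous scores (mid-ranks for ties). MSE is the mean squared difference
#' between one-hot targets and the raw two-column model outputs; when only
#' scalar scores are available (kNN neighbor fractions) it is computed against
#' the 0/1 positive-class target and flagged as not comparable to network MSE.
#' Ratios with zero denominators are reported as \code{NA} with a warning,
#' never as 0.
#'
#' @param labels factor (or 0/1) of true classes.
#' @param predictions factor (or 0/1) of predicted classes.
#' @param scores optional numeric positive-class scores for AUC.
#' @param outputs optional n x 2 matrix of raw model outputs for MSE.
#' @return An [EvalMetrics-class].
#' @examples
#' m <- computeMetrics(rep(c(1, 0), c(10, 10)),
#'                     rep(c(1, 0, 1, 0), c(8, 2, 3, 7)))
#' m
#' @export
computeMetrics <- function(labels, predictions, scores = NULL,
                           outputs = NULL) {
  labels <- coerceLabels(labels)
  predictions <- factor(as.character(predictions), levels = levels(labels))
  if (length(labels) != length(predictions))
    stop("labels and predictions must have the same length")
  if (!is.null(scores) && length(scores) != length(labels))
    stop("scores must have the same length as labels")
  pos <- levels(labels)[nlevels(labels)]
  isPos <- labels == pos
  predPos <- predictions == pos
  tp <- sum(isPos & predPos)
  fp <- sum(!isPos & predPos)
  fn <- sum(isPos & !predPos)
  tn <- sum(!isPos & !predPos)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  prec <- ratio(tp, tp + fp, "precision")
  acc <- ratio(tp + tn, length(labels), "accuracy")
  dice <- ratio(2 * tp, 2 * tp + fp + fn, "Dice score")
  auc <- NA_real_
  if (!is.null(scores) && any(isPos) && any(!isPos)) {
    r <- rank(scores)   # mid-ranks for ties
    n1 <- sum(isPos)
    auc <- (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!isPos))
  }
  mse <- NA_real_
  mseComparable <- FALSE
  onehot <- cbind(as.numeric(!isPos), as.numeric(isPos))
  if (!is.null(outputs)) {
    outputs <- as.matrix(outputs)
    if (!identical(dim(outputs), dim(onehot)))
      stop("outputs must be an n x 2 matrix")
    mse <- mean((onehot - outputs)^2)
    mseComparable <- TRUE
  } else if (!is.null(scores)) {
    mse <- mean((as.numeric(isPos) - scores)^2)
  }
  new("EvalMetrics", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), sensitivity = sens,
      accuracy = acc, precision = prec, auc = auc, dice = dice, mse = mse,
      mseComparable = mseComparable)
}

#' Render a cross-validation report
#'
#' One row per fold plus a pooled row computed from the pooled out-of-fold
#' confusion counts (the primary result). Percentages are rounded to two
#' decimals; AUC and Dice to four.
#'
#' @param cv a [CVResult-class].
#' @param datasetName character tag for the dataset column.
#' @param path optional CSV output path.
#' @return data.frame with columns \code{dataset, model, fold, n,
#'   sensitivity_pct, accuracy_pct, precision_pct, auc, dice, mse, n_hidden}.
#' @export
renderReport <- function(cv, datasetName = "dataset", path = NULL) {
  stopifnot(is(cv, "CVResult"))
  if (length(cv@labels) == 0L) stop("empty CV result")
  rows <- lapply(seq_along(cv@perFold), function(f) {
    idx <- cv@perFold[[f]]$test
    m <- suppressWarnings(computeMetrics(
      cv@labels[idx], cv@predictions[idx], cv@scores[idx],
      if (!is.null(cv@outputs)) cv@outputs[idx, , drop = FALSE]))
    metricRow(m, datasetName, cv@model, as.character(f), length(idx),
              cv@perFold[[f]]$nHidden)
  })
  pooledM <- suppressWarnings(computeMetrics(cv@labels, cv@predictions,
                                             cv@scores, cv@outputs))
  nh <- unlist(lapply(cv@perFold, `[[`, "nHidden"))
  rows <- c(rows, list(metricRow(pooledM, datasetName, cv@model, "pooled",
                                 length(cv@labels),
                                 if (length(nh)) max(nh) else NULL)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

metricRow <- function(m, dataset, model, fold, n, nHidden = NULL) {
  data.frame(dataset = dataset, model = model, fold = fold, n = n,
             sensitivity_pct = round(100 * m@sensitivity, 2),
             accuracy_pct = round(100 * m@accuracy, 2),
             precision_pct = round(100 * m@precision, 2),
             auc = round(m@auc, 4), dice = round(m@dice, 4),
             mse = m@mse,
             n_hidden = if (is.null(nHidden)) NA_integer_
                        else as.integer(nHidden),
             stringsAsFactors = FALSE)
}

#' Pooled metrics of a cross-validation result
#'
#' @param cv a [CVResult-class].
#' @return An [EvalMetrics-class] over the pooled out-of-fold predictions.
#' @export
pooledMetrics <- function(cv) {
  stopifnot(is(cv, "CVResult"))
  suppressWarnings(computeMetrics(cv@labels, cv@predictions, cv@scores,
                                  cv@outputs))
}
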