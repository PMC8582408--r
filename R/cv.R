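#' Stratified fold assignment
#'
#' Samples are shuffled within each class (from \code{seed}) and dealt
#' cyclically into folds, so fold sizes differ by at most one overall and per
#' class. Stratification protects against single-class test folds under the
#' severe class imbalance typical of lesion datasets.
#'
#' @param labels two-class factor.
#' @param folds integer number of folds (>= 2).
#' @param seed integer RNG seed; identical seeds give identical folds.
#' @return integer vector of fold ids in \code{1..folds}.
#' @examples
#' table(makeFolds(factor(rep(c("a", "b"), c(50, 53))), 5, seed = 1))
#' @export
makeFolds <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  if (any(table(labels) < folds))
    stop("every class needs at least as many samples as folds")
  set.seed(as.integer(seed))
  ord <- unlist(lapply(levels(labels), function(lv) sample(which(labels == lv))))
  assign <- integer(length(labels))
  assign[ord] <- rep_len(seq_len(folds), length(labels))
  assign
}

#' Run stratified k-fold cross-validation
#'
#' Retrains the chosen classifier on each training split and predicts the
#' left-out fold, so that pooled out-of-fold predictions cover every sample
#' exactly once. When \code{selectWithin = TRUE}, t-test feature selection is
#' refit inside each training split and applied to its test fold (leakage
#' guard); with \code{selectWithin = FALSE} the features are used as given,
#' matching workflows where selection happened globally beforehand.
#'
#' @param x a [LesionFeatureSet-class], or a numeric matrix with
#'   \code{labels}.
#' @param labels two-class factor (ignored when \code{x} is a feature set).
#' @param model \code{"knn"} or \code{"rbfnn"}.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the stratified fold assignment.
#' @param k neighbors for kNN (odd, default 5).
#' @param maxNeurons,mseGoal,spread,standardize RBFNN training controls, see
#'   [trainRBFNN()].
#' @param selectWithin run [ttestSelect()] inside each training fold
#'   (default FALSE).
#' @param alpha selection threshold used when \code{selectWithin = TRUE}.
#' @param foldAssign optional integer vector of fold ids in \code{1..folds},
#'   overriding the seed-derived stratified assignment.
#' @return A [CVResult-class].
#' @examples
#' tab <- twoClassTable(25, nInformative = 2, nNoise = 2, effect = 2, seed = 1)
#' cv <- runCV(tab, model = "knn", seed = 1)
#' table(pooledPredictions(cv), sampleLabels(tab))
#' @export
runCV <- function(x, labels = NULL, model = c("knn", "rbfnn"), folds = 5L,
                  seed = 1L, k = 5L, maxNeurons = 50L, mseGoal = 0.01,
                  spread = NULL, standardize = TRUE, selectWithin = FALSE,
                  alpha = 0.05, foldAssign = NULL) {
  model <- match.arg(model)
  if (is(x, "LesionFeatureSet")) {
    labels <- sampleLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("cross-validation needs two classes")
  n <- nrow(x)
  if (n < folds) stop("need at least as many samples as folds")
  assign <- if (is.null(foldAssign)) {
    makeFolds(labels, folds, seed)
  } else {
    stopifnot(length(foldAssign) == n, all(foldAssign %in% seq_len(folds)))
    as.integer(foldAssign)
  }

  predictions <- factor(rep(levels(labels)[1], n), levels = levels(labels))
  scores <- numeric(n)
  outputs <- if (model == "rbfnn") matrix(NA_real_, n, 2L) else NULL
  perFold <- vector("list", folds)

  for (f in seq_len(folds)) {
    testIdx <- which(assign == f)
    trainIdx <- which(assign != f)
    xtr <- x[trainIdx, , drop = FALSE]
    ytr <- labels[trainIdx]
    xte <- x[testIdx, , drop = FALSE]
    keep <- colnames(x)
    if (selectWithin) {
      sel <- ttestSelect(xtr, ytr, alpha = alpha)
      keep <- selectedFeatures(sel)
      if (length(keep) == 0L) {
        warning("fold ", f, ": no feature passed selection; keeping all")
        keep <- colnames(x)
      }
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    rec <- list(test = testIdx, features = keep)
    if (model == "knn") {
      pr <- knnPredict(xtr, ytr, xte, k = k)
    } else {
      fit <- trainRBFNN(xtr, ytr, maxNeurons = maxNeurons, mseGoal = mseGoal,
                        spread = spread, standardize = standardize)
      pr <- predictRBFNN(fit, xte)
      outputs[testIdx, ] <- pr$outputs
      rec$nHidden <- nrow(fit@centers)
      rec$finalMSE <- utils::tail(fit@mseTrajectory, 1L)
      rec$mseTrajectory <- fit@mseTrajectory
    }
    predictions[testIdx] <- pr$labels
    scores[testIdx] <- pr$scores
    perFold[[f]] <- rec
  }
  new("CVResult", folds = assign, labels = labels, predictions = predictions,
      scores = scores, outputs = outputs, perFold = perFold, model = model,
      seed = as.integer(seed))
}
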