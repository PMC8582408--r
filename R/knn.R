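#' k-nearest-neighbor prediction
#'
#' Majority vote among the \code{k} nearest training samples by Euclidean
#' distance. The score is the fraction of neighbors in the positive
#' (melanoma) class; distance ties at the neighborhood boundary are broken
#' deterministically by smaller training-sample index. \code{k} must be odd so
#' a two-class vote cannot tie.
#'
#' @param train numeric training matrix (samples x features) or a
#'   [LesionFeatureSet-class].
#' @param trainLabels two-class factor (ignored when \code{train} is a
#'   feature set).
#' @param query numeric matrix of query rows (or a single vector).
#' @param k odd integer number of neighbors, \code{1 <= k <= nrow(train)}.
#' @return list with \code{labels} (factor, levels as in training) and
#'   \code{scores} (numeric fraction of positive neighbors).
#' @examples
#' tr <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
#' knnPredict(tr, factor(c("a", "a", "b", "b")), c(0, 0.1), k = 1)
#' @export
knnPredict <- function(train, trainLabels = NULL, query, k = 5L) {
  if (is(train, "LesionFeatureSet")) {
    trainLabels <- sampleLabels(train)
    train <- featureMatrix(train)
  }
  train <- as.matrix(train)
  trainLabels <- as.factor(trainLabels)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  if (ncol(query) != ncol(train))
    stop("query and training dimensions do not match")
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(train)) stop("k must not exceed the number of training samples")
  if (k %% 2L == 0L) stop("k must be odd (two-class vote tie avoidance)")
  pos <- levels(trainLabels)[nlevels(trainLabels)]
  ## squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query^2), rowSums(train^2), "+") -
    2 * query %*% t(train)
  scores <- apply(d2, 1L, function(dr) {
    nb <- order(dr, seq_along(dr))[seq_len(k)]  # ties: smaller index first
    mean(trainLabels[nb] == pos)
  })
  labs <- factor(ifelse(scores > 0.5, pos, levels(trainLabels)[1]),
                 levels = levels(trainLabels))
  list(labels = labs, scores = as.numeric(scores))
}
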