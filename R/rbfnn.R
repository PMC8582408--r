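## Radial basis function network with Gaussian hidden units and a linear
## two-node output layer fit by least squares. Training adds hidden neurons
## greedily: at every step the training sample whose addition as a center most
## reduces the training MSE of the refit output layer becomes the next center.
## The candidate scoring is computed through an orthogonalized update, which
## gives exactly the same MSE reduction as a full least-squares refit with the
## candidate column appended (classical orthogonal least squares), just
## without redoing the factorization per candidate.

gaussActivations <- function(x, centers, spread) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * spread^2))
}

#' Train an RBF network by incremental center selection
#'
#' Targets are one-hot encoded (first class \code{(1, 0)}, second class
#' \code{(0, 1)}). Starting from a bias-only linear fit, hidden Gaussian
#' neurons centered on training samples are added one at a time, each chosen
#' to maximize the training-MSE reduction of the least-squares output layer;
#' training halts when the MSE reaches \code{mseGoal} or \code{maxNeurons}
#' centers have been added (or no candidate adds information). The recorded
#' MSE trajectory is therefore non-increasing, beginning with the 0-neuron
#' bias-only solution.
#'
#' @param x numeric training matrix (samples x features) or a
#'   [LesionFeatureSet-class].
#' @param labels two-class factor (ignored when \code{x} is a feature set).
#' @param maxNeurons maximum number of hidden neurons (default 50).
#' @param mseGoal target training MSE (default 0.01).
#' @param spread Gaussian width; default (\code{NULL}) is the median pairwise
#'   distance between training samples, a standard heuristic the source
#'   methodology leaves unspecified.
#' @param standardize z-score the inputs before training (default TRUE; the
#'   transform is stored in the model and applied to queries).
#' @return An [RBFNNModel-class].
#' @examples
#' xor <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
#' m <- trainRBFNN(xor, factor(c("a", "b", "b", "a")), maxNeurons = 4,
#'                 spread = 0.6, standardize = FALSE)
#' predictRBFNN(m, xor)$labels
#' @export
trainRBFNN <- function(x, labels = NULL, maxNeurons = 50L, mseGoal = 0.01,
                       spread = NULL, standardize = TRUE) {
  if (is(x, "LesionFeatureSet")) {
    labels <- sampleLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("training needs exactly two classes")
  n <- nrow(x)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  } else {
    ctr <- numeric(0)
    scl <- numeric(0)
  }
  if (is.null(spread)) {
    d <- stats::dist(x)
    spread <- stats::median(d[d > 0])
    if (!is.finite(spread) || spread <= 0) spread <- 1
  }
  if (spread <= 0) stop("spread must be positive")

  targets <- cbind(as.numeric(labels == levels(labels)[1]),
                   as.numeric(labels == levels(labels)[2]))
  ## orthonormal basis of the growing design matrix; bias column first
  Q <- matrix(1 / sqrt(n), n, 1L)
  E <- targets - Q %*% (t(Q) %*% targets)     # residuals
  mse <- mean(E^2)
  trajectory <- mse
  phi <- gaussActivations(x, x, spread)       # all candidate activations
  candidates <- seq_len(n)
  centerIdx <- integer(0)

  while (length(centerIdx) < maxNeurons && mse > mseGoal &&
         length(candidates) > 0L) {
    V <- phi[, candidates, drop = FALSE]
    W <- V - Q %*% (t(Q) %*% V)               # components orthogonal to span
    dn <- colSums(W^2)
    num <- rowSums((t(W) %*% E)^2)
    score <- ifelse(dn > 1e-10, num / dn, -Inf)
    best <- which.max(score)                  # ties: first (smallest index)
    if (!is.finite(score[best]) || score[best] <= 0) break
    w <- W[, best] / sqrt(dn[best])
    w <- w - Q %*% (t(Q) %*% w)               # re-orthogonalize for stability
    w <- w / sqrt(sum(w^2))
    Q <- cbind(Q, w)
    E <- E - w %*% (t(w) %*% E)
    mse <- mean(E^2)
    trajectory <- c(trajectory, mse)
    centerIdx <- c(centerIdx, candidates[best])
    candidates <- candidates[-best]
  }

  centers <- x[centerIdx, , drop = FALSE]
  A <- cbind(1, phi[, centerIdx, drop = FALSE])
  qrA <- qr(A)
  weights <- if (qrA$rank < ncol(A)) {
    warning("degenerate RBF design matrix; using ridge fallback ",
            "(regularizer 1e-8)")
    solve(crossprod(A) + diag(1e-8, ncol(A)), crossprod(A, targets))
  } else {
    qr.coef(qrA, targets)
  }
  new("RBFNNModel", centers = centers, spread = spread, weights = weights,
      mseTrajectory = trajectory, center = ctr, scale = scl,
      classLevels = levels(labels))
}

#' Predict with a trained RBF network
#'
#' The label is the class whose output node ("spike") is maximal; exact output
#' ties fall to the first (nevus) class and are reported via a message. The
#' score is the positive-class output min-max squashed to \code{[0, 1]} for
#' AUC use (rank-preserving).
#'
#' @param model an [RBFNNModel-class].
#' @param query numeric matrix of query rows (or a single vector).
#' @return list with \code{labels}, \code{scores} and the raw two-column
#'   \code{outputs}.
#' @export
predictRBFNN <- function(model, query) {
  stopifnot(is(model, "RBFNNModel"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  d <- if (length(model@center) > 0) length(model@center)
       else ncol(model@centers)
  if (ncol(query) != d && ncol(model@centers) > 0L)
    stop("query dimension does not match the model")
  if (length(model@center) > 0)
    query <- sweep(sweep(query, 2L, model@center), 2L, model@scale, "/")
  A <- if (nrow(model@centers) > 0L) {
    cbind(1, gaussActivations(query, model@centers, model@spread))
  } else {
    matrix(1, nrow(query), 1L)
  }
  Y <- A %*% model@weights
  ties <- Y[, 1] == Y[, 2]
  if (any(ties)) message(sum(ties), " tied output(s) assigned to the ",
                         model@classLevels[1], " class")
  labs <- factor(ifelse(Y[, 2] > Y[, 1], model@classLevels[2],
                        model@classLevels[1]),
                 levels = model@classLevels)
  s <- Y[, 2]
  rng <- range(s)
  scores <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1])
            else rep(0.5, length(s))
  list(labels = labs, scores = as.numeric(scores), outputs = Y)
}

#' Serialize / restore an RBF network as JSON
#'
#' @param model an [RBFNNModel-class].
#' @param path output (input) JSON path.
#' @return \code{writeRBFNN}: \code{path} invisibly; \code{readRBFNN}: an
#'   [RBFNNModel-class].
#' @export
writeRBFNN <- function(model, path) {
  stopifnot(is(model, "RBFNNModel"))
  jsonlite::write_json(
    list(centers = model@centers, spread = model@spread,
         weights = model@weights, mseTrajectory = model@mseTrajectory,
         center = model@center, scale = model@scale,
         classLevels = model@classLevels),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeRBFNN
#' @export
readRBFNN <- function(path) {
  j <- jsonlite::fromJSON(path)
  asMat <- function(m, ncols) {
    m <- as.matrix(m)
    if (length(m) == 0L) matrix(numeric(0), 0L, ncols) else m
  }
  new("RBFNNModel",
      centers = asMat(j$centers, length(j$center)),
      spread = j$spread,
      weights = as.matrix(j$weights),
      mseTrajectory = as.numeric(j$mseTrajectory),
      center = as.numeric(j$center), scale = as.numeric(j$scale),
      classLevels = as.character(j$classLevels))
}
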