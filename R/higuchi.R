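## 2D Higuchi surface fractal dimension.
##
## A channel is an M x N intensity matrix gamma (1-based indices here match
## the conventional 1-based surface notation; this is the single place where
## the index mapping is fixed). For scale k and offset m (1 <= m <= k) the
## subsampled matrix X_k^m keeps every k-th row/column starting at (m, m).
## The surface-area proxy A_m(k) multiplies the four absolute intensity
## differences along the edges of each k x k grid cell of X_k^m, sums over
## cells and normalizes by xi = 1/(2 k^4) * (N-1)/floor((N-m)/k)
## * (M-1)/floor((M-m)/k). A(k) averages A_m(k) over the k offsets, and the
## channel HFD is 1 plus the least-squares slope of ln A(k) against
## ln(1/k^2) (default fit scale).

#' Subsample a channel matrix at scale k and offset m
#'
#' Returns the matrix of entries \eqn{\gamma_{m + a k,\, m + b k}} for
#' \eqn{a = 0, \ldots, \lfloor (M-m)/k \rfloor} and
#' \eqn{b = 0, \ldots, \lfloor (N-m)/k \rfloor} (1-based indexing). At
#' \code{k = 1, m = 1} this is the full matrix: all points of the surface are
#' considered.
#'
#' @param gamma numeric M x N intensity matrix.
#' @param k integer scale, \code{1 <= k}.
#' @param m integer offset, \code{1 <= m <= k}.
#' @return the subsampled numeric matrix.
#' @examples
#' g <- outer(1:5, 1:5, function(i, j) 10 * i + j)
#' subsampleMatrix(g, k = 2, m = 1)
#' @export
subsampleMatrix <- function(gamma, k, m) {
  gamma <- checkChannel(gamma)
  checkScaleOffset(gamma, k, m)
  M <- nrow(gamma); N <- ncol(gamma)
  gamma[seq.int(m, M, by = k), seq.int(m, N, by = k), drop = FALSE]
}

#' Surface-area estimate at one scale and offset
#'
#' Computes \eqn{A_m(k)}: the normalized sum over the grid cells of
#' \eqn{X_k^m} of the product of four absolute neighbor differences. In
#' \code{"corrected"} mode the four factors are the differences along the four
#' edges of cell \eqn{(i, j)}; \code{"as_printed"} reproduces the typeset
#' variant in which the second factor compares against the fixed column
#' \eqn{m + k} (kept for auditability; it requires \eqn{m + k \le N}).
#'
#' @inheritParams subsampleMatrix
#' @param mode \code{"corrected"} (default) or \code{"as_printed"}.
#' @return numeric \eqn{A_m(k) \ge 0}.
#' @examples
#' g <- matrix(c(0, 1, 0, 1, 2, 1, 0, 1, 0), 3, byrow = TRUE)
#' areaEstimate(g, k = 1, m = 1)
#' @export
areaEstimate <- function(gamma, k, m, mode = c("corrected", "as_printed")) {
  gamma <- checkChannel(gamma)
  mode <- match.arg(mode)
  checkScaleOffset(gamma, k, m)
  M <- nrow(gamma); N <- ncol(gamma)
  P <- (M - m) %/% k          # cells along rows
  S <- (N - m) %/% k          # cells along columns
  if (P < 1L || S < 1L)
    stop("subsampled grid smaller than 2x2 at k = ", k, ", m = ", m)
  rows <- m + (0:P) * k
  cols <- m + (0:S) * k
  X <- gamma[rows, cols, drop = FALSE]
  TL <- X[1:P, 1:S, drop = FALSE]
  TR <- X[1:P, 2:(S + 1L), drop = FALSE]
  BL <- X[2:(P + 1L), 1:S, drop = FALSE]
  BR <- X[2:(P + 1L), 2:(S + 1L), drop = FALSE]
  f2 <- if (mode == "corrected") {
    abs(BR - TR)
  } else {
    if (m + k > N)
      stop("as_printed mode needs column m + k = ", m + k,
           " inside the matrix (N = ", N, ")")
    ## fixed reference column m + k, varying only with the cell row
    abs(BR - matrix(gamma[rows[1:P], m + k], P, S))
  }
  total <- sum(abs(TR - TL) * f2 * abs(BR - BL) * abs(BL - TL))
  xi <- 1 / (2 * k^4) * (N - 1) / S * (M - 1) / P
  xi * total
}

#' Offset-averaged surface-area estimate A(k)
#'
#' Arithmetic mean of \eqn{A_m(k)} over all offsets \eqn{m = 1, \ldots, k}.
#'
#' @inheritParams areaEstimate
#' @return numeric \eqn{A(k)}.
#' @export
averageArea <- function(gamma, k, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  mean(vapply(seq_len(k), function(m) areaEstimate(gamma, k, m, mode),
              numeric(1)))
}

#' Higuchi fractal dimension of one channel
#'
#' Computes \eqn{A(k)} for \eqn{k = 1, \ldots, k_{max}}, fits
#' \eqn{\ln A(k)} against \eqn{\ln(1/k^2)} (default fit scale) by ordinary
#' least squares, and reports the slope \eqn{S}, the fit \eqn{R^2}, and the
#' fractal dimension \eqn{HFD = S + 1}. A raw (unclamped) value is the
#' primary result; a copy clamped to the theoretical surface-dimension band
#' \code{[2, 3]} is reported alongside. Channels that are flat at any scale
#' (some \eqn{A(k) = 0}) carry no fractal information and raise an error.
#'
#' @param gamma numeric M x N intensity matrix with
#'   \code{min(M, N) >= kMax + 1}.
#' @param config an [HFDConfig-class] (default \code{hfdConfig()}).
#' @return list with \code{areas} (length \code{kMax}), \code{slope},
#'   \code{rSquared}, \code{hfd}, \code{hfdClamped}.
#' @examples
#' set.seed(1)
#' g <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
#' channelHFD(g)$hfd  # white noise estimates close to 3
#' @export
channelHFD <- function(gamma, config = hfdConfig()) {
  gamma <- checkChannel(gamma)
  stopifnot(is(config, "HFDConfig"))
  kMax <- config@kMax
  if (min(dim(gamma)) < kMax + 1L)
    stop("channel must be at least (kMax + 1) x (kMax + 1) = ",
         kMax + 1L, "x", kMax + 1L)
  ks <- seq_len(kMax)
  areas <- vapply(ks, function(k) averageArea(gamma, k, config@formulaMode),
                  numeric(1))
  zero <- areas <= 0
  if (any(zero))
    stop("degenerate surface: A(k) = 0 at k = ",
         paste(ks[zero], collapse = ", "),
         " (flat or near-flat channel)")
  x <- if (config@fitScale == "inverse_k_squared") log(1 / ks^2) else log(ks^2)
  y <- log(areas)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  ## constant ln A(k): the horizontal fit is exact but R^2 is undefined
  r2 <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)^2
  hfd <- slope + 1
  list(areas = areas, slope = slope, rSquared = r2, hfd = hfd,
       hfdClamped = min(3, max(2, hfd)))
}

#' Higuchi fractal dimension of an RGB image
#'
#' Runs [channelHFD()] on the R, G and B channels of the full rectangular
#' image and averages the three raw per-channel dimensions into the
#' \code{meanHFD} feature used downstream.
#'
#' @param image H x W x 3 numeric array with values in \code{[0, 255]}.
#' @param config an [HFDConfig-class].
#' @return An [HFDResult-class] object.
#' @examples
#' img <- fbmImage(32, hurst = 0.5, seed = 1)
#' res <- imageHFD(img)
#' meanHFD(res)
#' @export
imageHFD <- function(image, config = hfdConfig()) {
  image <- validateImage(image, minSize = config@kMax + 1L)
  chans <- c(R = 1L, G = 2L, B = 3L)
  res <- lapply(chans, function(ch) {
    tryCatch(channelHFD(image[, , ch], config),
             error = function(e) stop("channel ", names(chans)[ch], ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  hfds <- vapply(res, `[[`, numeric(1), "hfd")
  m <- mean(hfds)
  mc <- min(3, max(2, m))
  new("HFDResult", channels = res, meanHFD = m, meanHFDClamped = mc,
      clamped = !isTRUE(all.equal(m, mc)), config = config)
}

## internal checks ------------------------------------------------------------

checkChannel <- function(gamma) {
  if (is(gamma, "FBMSurface")) gamma <- gamma@grid
  if (!is.matrix(gamma) || !is.numeric(gamma))
    stop("channel must be a numeric matrix")
  ## force double: products of four 8-bit differences overflow 32-bit ints
  storage.mode(gamma) <- "double"
  if (anyNA(gamma)) stop("channel must not contain NA")
  gamma
}

checkScaleOffset <- function(gamma, k, m) {
  if (k < 1L || k != round(k)) stop("k must be a positive integer")
  if (m < 1L || m > k) stop("offset m must satisfy 1 <= m <= k")
  if (k > min(dim(gamma)) - 1L)
    stop("k must be at most min(M, N) - 1")
  invisible(TRUE)
}
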