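## Synthetic-data generators: fractional Brownian surfaces, lesions of known
## color composition, and two-class Gaussian feature tables. These define the
## ground-truth conditions every other module is tested against.

## internal: one spectral-synthesis fBm field using the current RNG stream.
## Power spectral density ~ f^-(2H+2), i.e. amplitude ~ f^-(H+1); random
## phases; the real part of the inverse FFT is an isotropic Gaussian field.
fbmField <- function(size, hurst) {
  n <- size
  ix <- (seq_len(n) - 1) / n
  ix[ix > 0.5] <- ix[ix > 0.5] - 1
  f <- sqrt(outer(ix^2, ix^2, "+"))
  amp <- matrix(0, n, n)
  amp[f > 0] <- f[f > 0]^(-(hurst + 1))
  phase <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  g <- Re(stats::fft(amp * exp(1i * phase), inverse = TRUE))
  rng <- range(g)
  if (rng[2] <= rng[1]) stop("degenerate spectral synthesis field")
  round((g - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Generate a fractional Brownian surface
#'
#' Fourier spectral synthesis of an isotropic fractional Brownian surface with
#' Hurst exponent \code{hurst}: spectral amplitudes \eqn{\propto f^{-(H+1)}}
#' with uniform random phases. The field is rescaled to \code{[0, 255]} and
#' rounded to integers so that it behaves like an 8-bit image channel
#' (rounding noise is deliberately part of the synthetic test conditions).
#' Smaller \code{hurst} gives rougher surfaces; the continuous-surface
#' theoretical fractal dimension is \eqn{3 - H}.
#'
#' @param size integer edge length (>= 16, so that at least \code{kMax = 8}
#'   scales are informative).
#' @param hurst Hurst exponent, strictly in (0, 1).
#' @param seed integer RNG seed; identical arguments give identical grids.
#' @return An [FBMSurface-class] object.
#' @examples
#' s <- fbmSurface(64, hurst = 0.5, seed = 1)
#' range(surfaceGrid(s))
#' theoreticalFD(s)
#' @export
fbmSurface <- function(size, hurst, seed) {
  if (size < 16L) stop("size must be at least 16 (too few scales for kMax = 8)")
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  set.seed(as.integer(seed))
  new("FBMSurface", grid = fbmField(size, hurst), hurst = hurst,
      seed = as.integer(seed))
}

#' Generate an RGB image of three independent fBm channels
#'
#' Three independent spectral-synthesis fields with a common Hurst exponent,
#' drawn from a single seeded RNG stream, assembled as an 8-bit RGB image.
#' Used to exercise the image-level HFD estimator on surfaces of known
#' roughness.
#'
#' @inheritParams fbmSurface
#' @return numeric \code{size} x \code{size} x 3 array in \code{[0, 255]}.
#' @examples
#' img <- fbmImage(32, hurst = 0.3, seed = 7)
#' dim(img)
#' @export
fbmImage <- function(size, hurst, seed) {
  if (size < 16L) stop("size must be at least 16 (too few scales for kMax = 8)")
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  set.seed(as.integer(seed))
  chans <- lapply(1:3, function(i) fbmField(size, hurst))
  array(c(chans[[1]], chans[[2]], chans[[3]]), c(size, size, 3L))
}

#' Generate a synthetic lesion of exactly known color composition
#'
#' Builds an elliptical lesion mask (optionally boundary-perturbed by random
#' radial harmonics) on a uniform skin-colored background, then colors the
#' in-mask pixels by drawing uniformly from the named color-cluster boxes so
#' that realized per-cluster pixel counts match the requested composition to
#' within one pixel (largest-remainder apportionment). The named boxes must be
#' pairwise disjoint, otherwise the ground-truth composition would be
#' ambiguous. The skin color is verified at generation time to fall outside
#' every box of \code{clusters}.
#'
#' @param size integer image edge length (>= 16).
#' @param clusters a [ColorClusterSet-class].
#' @param composition named numeric vector of fractions over cluster ids of
#'   \code{clusters}; must sum to 1 (tolerance 1e-9).
#' @param shapeRoughness numeric >= 0, amplitude of the radial boundary
#'   perturbation (0 = smooth ellipse; default 0.1).
#' @param seed integer RNG seed.
#' @param maskArea optional integer; when given, the mask is trimmed to
#'   exactly this many pixels (those with smallest normalized radius), which
#'   makes composition recovery exact at a known denominator.
#' @param skinColor integer RGB triple for the background (default
#'   \code{c(242, 230, 221)}); must lie outside every cluster box.
#' @return A [SyntheticLesion-class] object.
#' @examples
#' cs <- ColorClusterSet(data.frame(
#'   id = c("a", "b"), rmin = c(0, 100), rmax = c(40, 140),
#'   gmin = c(0, 60), gmax = c(40, 100), bmin = c(0, 30), bmax = c(40, 70)))
#' les <- syntheticLesion(48, cs, c(a = 0.5, b = 0.5), seed = 1)
#' sum(lesionMask(les))
#' @export
syntheticLesion <- function(size, clusters, composition, shapeRoughness = 0.1,
                            seed = 1L, maskArea = NULL,
                            skinColor = c(242L, 230L, 221L)) {
  if (size < 16L) stop("size must be at least 16")
  stopifnot(is(clusters, "ColorClusterSet"))
  ids <- names(composition)
  if (is.null(ids) || !all(ids %in% clusterIds(clusters)))
    stop("composition names must be cluster ids of the supplied set")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  boxes <- clusterBoxes(clusters)
  used <- boxes[match(ids, boxes$id), , drop = FALSE]
  ov <- overlappingBoxes(used)
  if (nrow(ov) > 0L)
    stop("named cluster boxes overlap (ground truth would be ambiguous): ",
         paste(ov$id1, "/", ov$id2, collapse = ", "))
  skinColor <- as.integer(round(skinColor))
  inAny <- vapply(seq_len(nrow(boxes)), function(i)
    pointInBox(skinColor, boxes[i, ]), logical(1))
  if (any(inAny))
    stop("skin color ", paste(skinColor, collapse = ","),
         " falls inside cluster box ", boxes$id[which(inAny)[1]])

  set.seed(as.integer(seed))
  ## normalized radius field: <= 1 inside the (perturbed) ellipse
  cy <- (size + 1) / 2
  cx <- (size + 1) / 2
  a <- 0.38 * size
  b <- 0.30 * size
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  rho <- sqrt((yy / a)^2 + (xx / b)^2)
  if (shapeRoughness > 0) {
    theta <- atan2(yy, xx)
    nh <- 4L
    ampl <- stats::runif(nh, 0, shapeRoughness / nh)
    phs <- stats::runif(nh, 0, 2 * pi)
    pert <- Reduce(`+`, lapply(seq_len(nh), function(h)
      ampl[h] * cos((h + 1) * theta + phs[h])))
    rho <- rho / (1 + pert)
  }
  if (is.null(maskArea)) {
    mask <- rho <= 1
  } else {
    maskArea <- as.integer(maskArea)
    if (maskArea < 1L || maskArea > size * size)
      stop("maskArea out of range")
    ord <- order(as.vector(rho))
    mask <- matrix(FALSE, size, size)
    mask[ord[seq_len(maskArea)]] <- TRUE
  }
  area <- sum(mask)
  if (area < length(composition))
    stop("mask too small for the requested composition")

  ## largest-remainder apportionment: counts within 1 px of fraction * area
  exact <- composition * area
  counts <- floor(exact)
  rem <- area - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }

  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- skinColor[ch]
  idx <- which(mask)           # column-major pixel indices into the mask
  idx <- sample(idx)           # random spatial interleaving of the clusters
  pos <- 1L
  npix <- size * size
  for (j in seq_along(ids)) {
    nj <- counts[j]
    if (nj == 0L) next
    px <- idx[pos:(pos + nj - 1L)]
    pos <- pos + nj
    bx <- used[j, ]
    runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, nj,
                                                  replace = TRUE) - 1L
    img[px]             <- runif_int(bx$rmin, bx$rmax)
    img[px + npix]      <- runif_int(bx$gmin, bx$gmax)
    img[px + 2L * npix] <- runif_int(bx$bmin, bx$bmax)
  }
  new("SyntheticLesion", image = img, mask = mask,
      composition = composition, counts = as.integer(counts),
      skinColor = skinColor, seed = as.integer(seed))
}

## internal: pairs of boxes with a common point (inclusive bounds)
overlappingBoxes <- function(boxes) {
  out <- data.frame(id1 = character(), id2 = character())
  n <- nrow(boxes)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- boxes[i, ]; bj <- boxes[j, ]
    if (bi$rmin <= bj$rmax && bj$rmin <= bi$rmax &&
        bi$gmin <= bj$gmax && bj$gmin <= bi$gmax &&
        bi$bmin <= bj$bmax && bj$bmin <= bi$bmax)
      out <- rbind(out, data.frame(id1 = bi$id, id2 = bj$id))
  }
  out
}

pointInBox <- function(rgb, box) {
  rgb[1] >= box$rmin && rgb[1] <= box$rmax &&
    rgb[2] >= box$gmin && rgb[2] <= box$gmax &&
    rgb[3] >= box$bmin && rgb[3] <= box$bmax
}

#' Generate a two-class Gaussian feature table
#'
#' Class-conditional Gaussian features with unit standard deviation.
#' Informative columns shift the melanoma class mean by
#' \code{effect} standard deviations; noise columns are identically
#' distributed in both classes. Labels are \code{nevus}/\code{melanoma},
#' \code{nPerClass} each.
#'
#' @param nPerClass integer >= 2 samples per class.
#' @param nInformative,nNoise integer column counts (their sum must be >= 1).
#' @param effect numeric standardized mean shift of the informative columns.
#' @param seed integer RNG seed.
#' @return A [TwoClassTable-class] object (a [LesionFeatureSet-class] with
#'   ground-truth \code{effectSizes}).
#' @examples
#' tab <- twoClassTable(20, nInformative = 2, nNoise = 3, effect = 1, seed = 1)
#' dim(featureMatrix(tab))
#' table(sampleLabels(tab))
#' @export
twoClassTable <- function(nPerClass, nInformative, nNoise, effect, seed = 1L) {
  if (nPerClass < 2L) stop("nPerClass must be at least 2")
  d <- nInformative + nNoise
  if (d < 1L) stop("at least one feature column is required")
  set.seed(as.integer(seed))
  n <- 2L * nPerClass
  x <- matrix(stats::rnorm(n * d), n, d)
  labels <- factor(rep(c("nevus", "melanoma"), each = nPerClass),
                   levels = c("nevus", "melanoma"))
  if (nInformative > 0L)
    x[labels == "melanoma", seq_len(nInformative)] <-
      x[labels == "melanoma", seq_len(nInformative)] + effect
  colnames(x) <- paste0("f", seq_len(d))
  effects <- c(rep(effect, nInformative), rep(0, nNoise))
  new("TwoClassTable", features = x, labels = labels,
      effectSizes = effects, seed = as.integer(seed))
}

#' Write a synthetic lesion to disk
#'
#' Writes the RGB image and binary mask as PNG plus a JSON sidecar carrying
#' the ground truth (composition, realized counts, seed, skin color).
#'
#' @param lesion a [SyntheticLesion-class].
#' @param imagePath,maskPath,jsonPath output paths; \code{maskPath} and
#'   \code{jsonPath} default to \code{imagePath} with suffixes
#'   \code{_mask.png} / \code{.json}.
#' @return named character vector of the written paths, invisibly.
#' @export
writeLesion <- function(lesion, imagePath,
                        maskPath = sub("\\.png$", "_mask.png", imagePath),
                        jsonPath = sub("\\.png$", ".json", imagePath)) {
  stopifnot(is(lesion, "SyntheticLesion"))
  writeRGBImage(lesion@image, imagePath)
  writeMask(lesion@mask, maskPath)
  jsonlite::write_json(
    list(composition = as.list(lesion@composition),
         counts = as.list(stats::setNames(lesion@counts,
                                          names(lesion@composition))),
         maskArea = sum(lesion@mask),
         skinColor = lesion@skinColor, seed = lesion@seed),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(image = imagePath, mask = maskPath, json = jsonPath))
}

#' Write a fractional Brownian surface to disk
#'
#' Greyscale PNG (the grid replicated on three channels) plus a JSON sidecar
#' with the generating Hurst exponent and seed.
#'
#' @param surface an [FBMSurface-class].
#' @param imagePath,jsonPath output paths.
#' @return named character vector of the written paths, invisibly.
#' @export
writeSurface <- function(surface, imagePath,
                         jsonPath = sub("\\.png$", ".json", imagePath)) {
  stopifnot(is(surface, "FBMSurface"))
  g <- surface@grid
  writeRGBImage(array(rep(g, 3L), c(dim(g), 3L)), imagePath)
  jsonlite::write_json(
    list(hurst = surface@hurst, theoreticalFD = 3 - surface@hurst,
         seed = surface@seed),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(image = imagePath, json = jsonPath))
}
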