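## Pre-processing: hair removal and lesion segmentation. The upstream
## literature rarely states these algorithms precisely, so standard,
## replaceable building blocks are used: a DullRazor-style morphological
## bottom-hat over oriented linear structuring elements followed by
## neighborhood inpainting, and Otsu thresholding with
## largest-connected-component extraction. The pipeline accepts externally
## supplied masks, so segmentation quality never blocks feature extraction.

## internal: offsets (drow, dcol) of a digital line of odd length, angle in
## degrees. Used as a structuring element for grayscale min/max filtering.
lineOffsets <- function(len = 11L, angleDeg = 0) {
  len <- as.integer(len)
  if (len %% 2L == 0L) len <- len + 1L
  half <- (len - 1L) / 2L
  th <- angleDeg * pi / 180
  off <- unique(cbind(round((-half:half) * sin(th)),
                      round((-half:half) * cos(th))))
  off
}

## internal: shift a matrix by (dr, dc), padding with `fill`
shiftMatrix <- function(x, dr, dc, fill) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  rs <- seq_len(n) - dr
  cs <- seq_len(m) - dc
  okr <- rs >= 1L & rs <= n
  okc <- cs >= 1L & cs <= m
  out[okr, okc] <- x[rs[okr], cs[okc]]
  out
}

## internal: grayscale erosion (min) / dilation (max) over a set of offsets.
## Implemented by shifting rather than EBImage's morphology, which operates on
## [0, 1] intensities only.
grayErode <- function(x, off) {
  out <- x
  for (i in seq_len(nrow(off)))
    out <- pmin(out, shiftMatrix(x, off[i, 1], off[i, 2], Inf))
  out
}

grayDilate <- function(x, off) {
  out <- x
  for (i in seq_len(nrow(off)))
    out <- pmax(out, shiftMatrix(x, off[i, 1], off[i, 2], -Inf))
  out
}

#' Remove hair-like structures from a lesion image
#'
#' Detects dark elongated structures with a grayscale morphological bottom-hat
#' (closing minus image) taken as the maximum response over a set of oriented
#' linear structuring elements, thresholds the response at
#' \code{lineStrength}, dilates the detected strokes by one pixel, and
#' replaces the covered pixels by iterative inpainting from the mean of their
#' already-known 8-neighbors. Pixels not on detected hair are unchanged; an
#' image without detected hair is returned as an identical copy.
#'
#' @param image H x W x 3 array in \code{[0, 255]}.
#' @param lineStrength numeric detection threshold on the bottom-hat response
#'   in intensity units (default 20).
#' @param lineLength integer length in pixels of the oriented structuring
#'   elements (default 11; strokes up to roughly this width are removed).
#' @param angles numeric vector of orientations in degrees.
#' @return H x W x 3 array with hair pixels inpainted.
#' @examples
#' img <- array(200, c(32, 32, 3))
#' identical(removeHair(img), img)  # nothing to remove
#' @export
removeHair <- function(image, lineStrength = 20, lineLength = 11L,
                       angles = seq(0, 150, by = 30)) {
  image <- validateImage(image)
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  response <- matrix(0, nrow(gray), ncol(gray))
  for (a in angles) {
    off <- lineOffsets(lineLength, a)
    bh <- grayErode(grayDilate(gray, off), off) - gray   # bottom-hat
    response <- pmax(response, bh)
  }
  hair <- response > lineStrength
  ## keep only elongated detections: a hair must span at least the length of
  ## the structuring elements; short slivers (e.g. lesion-boundary curvature)
  ## are not hair
  if (any(hair)) {
    lab <- EBImage::bwlabel(hair)
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      span <- max(diff(range(px[, 1])), diff(range(px[, 2]))) + 1L
      if (span < lineLength) hair[px] <- FALSE
    }
  }
  if (!any(hair)) return(image)
  nb8 <- as.matrix(expand.grid(-1:1, -1:1))
  hair <- grayDilate(hair * 1, nb8) > 0
  out <- image
  for (ch in 1:3) out[, , ch] <- inpaintMask(out[, , ch], hair)
  out
}

## internal: iterative mean-of-known-neighbors fill over masked pixels
inpaintMask <- function(chan, mask) {
  known <- !mask
  vals <- chan
  vals[mask] <- 0
  kern <- matrix(1, 3, 3)
  while (any(!known)) {
    s <- EBImage::filter2(vals * known, kern, boundary = 0)
    cnt <- EBImage::filter2(known * 1, kern, boundary = 0)
    front <- !known & cnt > 0.5
    if (!any(front)) break   # isolated region; cannot happen with 3x3 kernel
    vals[front] <- s[front] / cnt[front]
    known[front] <- TRUE
  }
  pmin(pmax(round(vals), 0), 255)
}

#' Segment the lesion by global thresholding
#'
#' Otsu threshold on the luminance channel (unweighted mean of R, G, B); the
#' darker side is taken as lesion, the largest connected component is kept and
#' its holes are filled, so the returned mask always has exactly one connected
#' component with no holes.
#'
#' @param image H x W x 3 array in \code{[0, 255]}.
#' @return logical H x W lesion mask (\code{TRUE} = lesion); its pixel count
#'   is \code{sum(mask)}.
#' @examples
#' cs <- ColorClusterSet(data.frame(id = "dark", rmin = 20, rmax = 60,
#'   gmin = 10, gmax = 50, bmin = 10, bmax = 50))
#' les <- syntheticLesion(48, cs, c(dark = 1), shapeRoughness = 0, seed = 1)
#' mask <- segmentLesion(lesionImage(les))
#' sum(mask & lesionMask(les)) / sum(mask | lesionMask(les)) # near 1
#' @export
segmentLesion <- function(image) {
  image <- validateImage(image)
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3 / 255
  if (diff(range(lum)) < .Machine$double.eps)
    stop("segmentation failure: constant image has no foreground")
  thr <- EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
  mask <- lum < thr
  if (!any(mask))
    stop("segmentation failure: empty foreground after thresholding")
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  mask
}
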