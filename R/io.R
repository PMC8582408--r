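#' Read an RGB image as an 8-bit intensity array
#'
#' Reads PNG (via \pkg{png}) or JPEG/TIFF (via \pkg{EBImage}) into the
#' package's internal representation: an H x W x 3 numeric array of integer
#' intensities in \code{[0, 255]}, row-major with 0-based pixel coordinates
#' mapped to 1-based R indices. Greyscale inputs are replicated across the
#' three channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return numeric H x W x 3 array with values in \code{[0, 255]}.
#' @seealso [writeRGBImage()], [readMask()]
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
  } else {
    im <- EBImage::readImage(path)
    d <- dim(im)
    x <- if (length(d) == 2L) t(im@.Data) else aperm(im@.Data, c(2L, 1L, 3L))
  }
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  validateImage(round(x * 255))
}

#' Write an RGB image array to PNG
#'
#' @param image H x W x 3 array with values in \code{[0, 255]}.
#' @param path output path (PNG).
#' @return \code{path}, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  image <- validateImage(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read / write a binary lesion mask
#'
#' Masks are stored as single-channel PNG with values 0/255; pixels above 127
#' are read as lesion (\code{TRUE}).
#'
#' @param path file path.
#' @return \code{readMask}: a logical H x W matrix.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' @param mask logical H x W matrix.
#' @rdname readMask
#' @return \code{writeMask}: \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

## internal: check/coerce the H x W x 3, [0,255] contract (min size 16 per
## the image type invariants; the HFD estimator separately requires
## min(M, N) >= kMax + 1).
validateImage <- function(image, minSize = 16L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (dim(image)[1] < minSize || dim(image)[2] < minSize)
    stop("image must be at least ", minSize, "x", minSize, " pixels")
  storage.mode(image) <- "double"
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("image intensities must lie in [0, 255]")
  image
}
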