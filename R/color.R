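## Color-cluster features: map lesion pixels to RGB boxes and compute the
## percentage of the lesion area occupied by each cluster.

#' Load a color-cluster set from CSV or JSON
#'
#' CSV files need a header \code{id,rmin,rmax,gmin,gmax,bmin,bmax}; JSON files
#' hold an array of objects with the same fields. The set is validated (bounds
#' in \code{[0, 255]}, \code{min <= max} per channel, unique ids) and
#' malformed entries are reported by cluster id.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @return A [ColorClusterSet-class].
#' @seealso [defaultClusterSet()]
#' @export
loadClusterSet <- function(path) {
  if (!file.exists(path)) stop("cluster config file not found: ", path)
  boxes <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ColorClusterSet(boxes)
}

#' The packaged default 23-cluster set
#'
#' A pairwise-disjoint set of 23 axis-aligned RGB boxes spanning the colors of
#' pigmented skin lesions: black, a ten-step brown ramp, blue-gray shades,
#' reds, pinks and whites. The widely used 23-cluster palette for melanocytic
#' lesions is defined only graphically in the literature, so this package
#' ships its own editable default; all analyses are defined with respect to
#' whatever set is loaded.
#'
#' @return A [ColorClusterSet-class] with 23 boxes \code{cl1} ... \code{cl23}.
#' @examples
#' nClusters(defaultClusterSet())
#' @export
defaultClusterSet <- function() {
  loadClusterSet(system.file("extdata", "color_clusters_23.csv",
                             package = "fractalDerm", mustWork = TRUE))
}

#' Subset a cluster set by id
#'
#' @param clusters a [ColorClusterSet-class].
#' @param ids character vector of cluster ids to keep, in the given order.
#' @return A [ColorClusterSet-class] with the requested boxes.
#' @export
subsetClusters <- function(clusters, ids) {
  stopifnot(is(clusters, "ColorClusterSet"))
  boxes <- clusterBoxes(clusters)
  miss <- setdiff(ids, boxes$id)
  if (length(miss) > 0L)
    stop("unknown cluster id: ", paste(miss, collapse = ", "))
  ColorClusterSet(boxes[match(ids, boxes$id), , drop = FALSE])
}

#' Assign one pixel to a color cluster
#'
#' Returns the id of the first cluster (in list order) whose box contains the
#' pixel inclusively on all three channels, or \code{NA} if no box contains
#' it. The first-match rule makes assignment deterministic for overlapping
#' custom sets.
#'
#' @param rgb integer triple in \code{[0, 255]}.
#' @param clusters a [ColorClusterSet-class].
#' @return cluster id (character) or \code{NA_character_}.
#' @examples
#' assignPixel(c(5, 5, 5), defaultClusterSet())
#' @export
assignPixel <- function(rgb, clusters) {
  stopifnot(is(clusters, "ColorClusterSet"))
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || anyNA(rgb) || any(rgb < 0) || any(rgb > 255))
    stop("rgb must be a triple in [0, 255]")
  b <- clusterBoxes(clusters)
  hit <- rgb[1] >= b$rmin & rgb[1] <= b$rmax &
         rgb[2] >= b$gmin & rgb[2] <= b$gmax &
         rgb[3] >= b$bmin & rgb[3] <= b$bmax
  if (any(hit)) b$id[which(hit)[1]] else NA_character_
}

#' Percentage of lesion area per color cluster
#'
#' For each cluster, the percentage of in-mask pixels whose RGB value falls in
#' the cluster's box (first-match rule for overlapping boxes): 100 times the
#' cluster pixel count divided by the mask area. Pixels matching no box are
#' accumulated in \code{unassigned}; assigned plus unassigned counts equal the
#' mask area exactly, so the returned percentages sum to 100.
#'
#' @param image H x W x 3 array in \code{[0, 255]}.
#' @param mask logical H x W matrix with at least one \code{TRUE} pixel.
#' @param clusters a [ColorClusterSet-class].
#' @return named numeric vector: one percentage per cluster id plus
#'   \code{unassigned}.
#' @examples
#' cs <- defaultClusterSet()
#' les <- syntheticLesion(48, cs, c(cl2 = 0.6, cl5 = 0.4), seed = 3)
#' clusterPercentages(lesionImage(les), lesionMask(les), cs)
#' @export
clusterPercentages <- function(image, mask, clusters) {
  image <- validateImage(image)
  stopifnot(is(clusters, "ColorClusterSet"))
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix")
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("mask shape must match the image")
  area <- sum(mask)
  if (area < 1L) stop("mask area must be at least 1 pixel")
  r <- image[, , 1][mask]
  g <- image[, , 2][mask]
  bl <- image[, , 3][mask]
  b <- clusterBoxes(clusters)
  unassigned <- rep(TRUE, area)
  counts <- integer(nrow(b))
  for (i in seq_len(nrow(b))) {
    hit <- unassigned &
      r >= b$rmin[i] & r <= b$rmax[i] &
      g >= b$gmin[i] & g <= b$gmax[i] &
      bl >= b$bmin[i] & bl <= b$bmax[i]
    counts[i] <- sum(hit)
    unassigned <- unassigned & !hit
  }
  pct <- 100 * counts / area
  stats::setNames(c(pct, 100 * sum(unassigned) / area),
                  c(b$id, "unassigned"))
}
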