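#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ColorClusterSet
## ---------------------------------------------------------------------------

#' Set of RGB color-cluster boxes
#'
#' A \code{ColorClusterSet} holds an ordered list of axis-aligned boxes in
#' 8-bit RGB space. Each box has an id and inclusive per-channel
#' \code{[min, max]} bounds; a lesion pixel belongs to the first box (in list
#' order) that contains it on all three channels. The canonical analysis set
#' has 23 boxes (\code{cl1} ... \code{cl23}) but any number is allowed for
#' custom sets.
#'
#' @slot boxes a \code{data.frame} with columns \code{id}, \code{rmin},
#'   \code{rmax}, \code{gmin}, \code{gmax}, \code{bmin}, \code{bmax}.
#' @seealso [loadClusterSet()], [defaultClusterSet()], [clusterPercentages()]
#' @export
setClass("ColorClusterSet", representation(boxes = "data.frame"))

setValidity("ColorClusterSet", function(object) {
  b <- object@boxes
  need <- c("id", "rmin", "rmax", "gmin", "gmax", "bmin", "bmax")
  if (!all(need %in% colnames(b)))
    return(paste("boxes must have columns:", paste(need, collapse = ", ")))
  if (nrow(b) < 1L) return("at least one cluster box is required")
  if (anyDuplicated(b$id))
    return(paste0("duplicate cluster id: ",
                  paste(unique(b$id[duplicated(b$id)]), collapse = ", ")))
  num <- as.matrix(b[, need[-1]])
  if (any(!is.finite(num)) || any(num < 0) || any(num > 255))
    return("channel bounds must be finite integers in [0, 255]")
  for (ch in c("r", "g", "b")) {
    bad <- b[[paste0(ch, "min")]] > b[[paste0(ch, "max")]]
    if (any(bad))
      return(paste0("min > max on channel ", toupper(ch), " for cluster: ",
                    paste(b$id[bad], collapse = ", ")))
  }
  TRUE
})

#' Construct a ColorClusterSet
#'
#' @param boxes data.frame with columns \code{id, rmin, rmax, gmin, gmax,
#'   bmin, bmax}; bounds are inclusive integers in \code{[0, 255]}.
#' @return A validated [ColorClusterSet-class] object.
#' @examples
#' ColorClusterSet(data.frame(id = "dark", rmin = 0, rmax = 60,
#'                            gmin = 0, gmax = 60, bmin = 0, bmax = 60))
#' @export
ColorClusterSet <- function(boxes) {
  boxes <- as.data.frame(boxes, stringsAsFactors = FALSE)
  boxes$id <- as.character(boxes$id)
  for (cc in c("rmin", "rmax", "gmin", "gmax", "bmin", "bmax"))
    boxes[[cc]] <- as.integer(round(boxes[[cc]]))
  rownames(boxes) <- NULL
  new("ColorClusterSet", boxes = boxes)
}

#' @rdname accessors
#' @export
setMethod("clusterBoxes", "ColorClusterSet", function(x) x@boxes)

#' @rdname accessors
#' @export
setMethod("clusterIds", "ColorClusterSet", function(x) x@boxes$id)

#' @rdname accessors
#' @export
setMethod("nClusters", "ColorClusterSet", function(x) nrow(x@boxes))

## ---------------------------------------------------------------------------
## LesionFeatureSet
## ---------------------------------------------------------------------------

#' Feature matrix with binary lesion labels
#'
#' Samples-by-features numeric matrix paired with a two-level factor of
#' lesion labels (\code{nevus} vs \code{melanoma}; the second level is the
#' positive class for every metric in the package).
#'
#' @slot features numeric matrix, samples in rows, named feature columns.
#' @slot labels factor of length \code{nrow(features)}.
#' @export
setClass("LesionFeatureSet",
         representation(features = "matrix", labels = "factor"))

setValidity("LesionFeatureSet", function(object) {
  if (!is.numeric(object@features)) return("features must be numeric")
  if (nrow(object@features) != length(object@labels))
    return("nrow(features) must equal length(labels)")
  if (is.null(colnames(object@features)) ||
      anyDuplicated(colnames(object@features)))
    return("features must have unique column names")
  if (anyNA(object@features)) return("features must not contain NA")
  if (nlevels(object@labels) > 2L)
    return("labels must have at most two levels")
  TRUE
})

#' Construct a LesionFeatureSet
#'
#' @param features numeric matrix (samples x features) with column names.
#' @param labels factor or character/0-1 vector of per-sample class labels;
#'   coerced to a factor whose second level is the positive (melanoma) class.
#' @return A [LesionFeatureSet-class] object.
#' @export
LesionFeatureSet <- function(features, labels) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- coerceLabels(labels)
  new("LesionFeatureSet", features = features, labels = labels)
}

## internal: normalize label encodings; keeps nevus < melanoma ordering when
## those names are used, otherwise the natural factor level order.
coerceLabels <- function(labels) {
  if (is.factor(labels)) return(labels)
  labels <- as.character(labels)
  if (all(labels %in% c("nevus", "melanoma")))
    factor(labels, levels = c("nevus", "melanoma"))
  else if (all(labels %in% c("0", "1")))
    factor(labels, levels = c("0", "1"))
  else
    factor(labels)
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "LesionFeatureSet", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "LesionFeatureSet", function(x) x@labels)

#' @describeIn LesionFeatureSet number of samples.
#' @param x a \code{LesionFeatureSet}.
#' @export
setMethod("nrow", "LesionFeatureSet", function(x) nrow(x@features))

#' @describeIn LesionFeatureSet number of features.
#' @export
setMethod("ncol", "LesionFeatureSet", function(x) ncol(x@features))

## ---------------------------------------------------------------------------
## TwoClassTable (synthetic feature tables)
## ---------------------------------------------------------------------------

#' Synthetic two-class feature table
#'
#' A [LesionFeatureSet-class] generated by [twoClassTable()] carrying the
#' per-feature true effect sizes and the generator seed as ground truth.
#'
#' @slot effectSizes numeric, true standardized mean shift per feature.
#' @slot seed integer generator seed.
#' @export
setClass("TwoClassTable", contains = "LesionFeatureSet",
         representation(effectSizes = "numeric", seed = "integer"))

setValidity("TwoClassTable", function(object) {
  if (length(object@effectSizes) != ncol(object@features))
    return("effectSizes must have one entry per feature")
  TRUE
})

## ---------------------------------------------------------------------------
## FBMSurface
## ---------------------------------------------------------------------------

#' Fractional Brownian surface
#'
#' A synthetic intensity surface of controllable roughness generated by
#' Fourier spectral synthesis (power spectral density proportional to
#' \eqn{f^{-(2H+2)}}). The Hurst exponent \eqn{H \in (0,1)} controls
#' smoothness; the theoretical fractal dimension of the continuous surface is
#' \eqn{3 - H}. Grids are rescaled to \code{[0, 255]} and rounded to integers
#' to mimic 8-bit image channels.
#'
#' @slot grid numeric matrix of intensities in \code{[0, 255]}.
#' @slot hurst numeric Hurst exponent in (0, 1).
#' @slot seed integer RNG seed used for the phase field.
#' @seealso [fbmSurface()], [fbmImage()]
#' @export
setClass("FBMSurface",
         representation(grid = "matrix", hurst = "numeric", seed = "integer"))

setValidity("FBMSurface", function(object) {
  if (!all(is.finite(object@grid))) return("grid must be finite everywhere")
  if (object@hurst <= 0 || object@hurst >= 1)
    return("hurst must lie strictly in (0, 1)")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("surfaceGrid", "FBMSurface", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("hurst", "FBMSurface", function(x) x@hurst)

#' @rdname accessors
#' @export
setMethod("theoreticalFD", "FBMSurface", function(x) 3 - x@hurst)

## ---------------------------------------------------------------------------
## SyntheticLesion
## ---------------------------------------------------------------------------

#' Synthetic lesion image with known color composition
#'
#' An RGB image containing an elliptical (optionally boundary-perturbed)
#' lesion whose in-mask pixels are drawn uniformly from named color-cluster
#' boxes according to an exactly realized composition; out-of-mask pixels take
#' a reserved skin color verified to fall outside every box of the generating
#' set.
#'
#' @slot image integer array H x W x 3, values in \code{[0, 255]}.
#' @slot mask logical H x W matrix (TRUE = lesion).
#' @slot composition named numeric vector of per-cluster fractions (sums to 1).
#' @slot counts named integer vector of realized per-cluster pixel counts.
#' @slot skinColor integer length-3 RGB background color.
#' @slot seed integer generator seed.
#' @seealso [syntheticLesion()]
#' @export
setClass("SyntheticLesion",
         representation(image = "array", mask = "matrix",
                        composition = "numeric", counts = "integer",
                        skinColor = "integer", seed = "integer"))

setValidity("SyntheticLesion", function(object) {
  if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
    return("image must be an H x W x 3 array")
  if (!identical(dim(object@image)[1:2], dim(object@mask)))
    return("mask must have the same H x W shape as the image")
  if (abs(sum(object@composition) - 1) > 1e-9)
    return("composition fractions must sum to 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("lesionImage", "SyntheticLesion", function(x) x@image)

#' @rdname accessors
#' @export
setMethod("lesionMask", "SyntheticLesion", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("composition", "SyntheticLesion", function(x) x@composition)

## ---------------------------------------------------------------------------
## HFDConfig / HFDResult
## ---------------------------------------------------------------------------

#' Configuration for the 2D Higuchi estimator
#'
#' @slot kMax integer maximal fractal scale (default 8).
#' @slot formulaMode \code{"corrected"} (default) uses the four cell-edge
#'   absolute differences; \code{"as_printed"} reproduces the typeset variant
#'   whose second factor has a fixed column index (retained for audit).
#' @slot fitScale abscissa of the log-log fit: \code{"inverse_k_squared"}
#'   (default, regress \eqn{\ln A(k)} on \eqn{\ln(1/k^2)}) or
#'   \code{"k_squared"}.
#' @seealso [hfdConfig()], [channelHFD()], [imageHFD()]
#' @export
setClass("HFDConfig",
         representation(kMax = "integer", formulaMode = "character",
                        fitScale = "character"))

setValidity("HFDConfig", function(object) {
  if (object@kMax < 2L) return("kMax must be at least 2")
  if (!object@formulaMode %in% c("corrected", "as_printed"))
    return("formulaMode must be 'corrected' or 'as_printed'")
  if (!object@fitScale %in% c("inverse_k_squared", "k_squared"))
    return("fitScale must be 'inverse_k_squared' or 'k_squared'")
  TRUE
})

#' Create an HFD estimator configuration
#'
#' @param kMax integer, maximal scale (default 8); every analyzed channel
#'   must satisfy \code{min(M, N) >= kMax + 1}.
#' @param formulaMode,fitScale see [HFDConfig-class].
#' @return An [HFDConfig-class] object.
#' @examples
#' hfdConfig()
#' hfdConfig(kMax = 4, formulaMode = "as_printed")
#' @export
hfdConfig <- function(kMax = 8L,
                      formulaMode = c("corrected", "as_printed"),
                      fitScale = c("inverse_k_squared", "k_squared")) {
  new("HFDConfig", kMax = as.integer(kMax),
      formulaMode = match.arg(formulaMode), fitScale = match.arg(fitScale))
}

#' Per-image 2D Higuchi fractal dimension result
#'
#' @slot channels named list (R, G, B); each element is a list with
#'   \code{areas} (the k-averaged surface-area estimates \eqn{A(k)}),
#'   \code{slope}, \code{rSquared}, \code{hfd} (raw, unclamped) and
#'   \code{hfdClamped} (raw value clamped to \code{[2, 3]}).
#' @slot meanHFD numeric, arithmetic mean of the three raw per-channel HFDs;
#'   this is the downstream classification feature.
#' @slot meanHFDClamped numeric, mean HFD clamped to \code{[2, 3]}.
#' @slot clamped logical, TRUE when clamping changed the mean value.
#' @slot config the [HFDConfig-class] used.
#' @export
setClass("HFDResult",
         representation(channels = "list", meanHFD = "numeric",
                        meanHFDClamped = "numeric", clamped = "logical",
                        config = "HFDConfig"))

#' @rdname accessors
#' @export
setMethod("meanHFD", "HFDResult", function(x) x@meanHFD)

#' @rdname accessors
#' @export
setMethod("hfdChannels", "HFDResult", function(x) x@channels)

## ---------------------------------------------------------------------------
## SelectionResult
## ---------------------------------------------------------------------------

#' Per-feature t-test selection report
#'
#' @slot table data.frame with columns \code{feature}, \code{t}, \code{p},
#'   \code{selected}, \code{flagged} (TRUE when the statistic was undefined,
#'   e.g. zero variance in both groups).
#' @slot alpha numeric significance threshold; selection is strict
#'   \code{p < alpha}.
#' @export
setClass("SelectionResult",
         representation(table = "data.frame", alpha = "numeric"))

#' @rdname accessors
#' @export
setMethod("selectionTable", "SelectionResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SelectionResult",
          function(x) x@table$feature[x@table$selected])

## ---------------------------------------------------------------------------
## RBFNNModel
## ---------------------------------------------------------------------------

#' Radial basis function network model
#'
#' Gaussian-kernel RBF network with two linear output nodes (one per class)
#' fit by least squares, trained by greedy incremental center selection.
#'
#' @slot centers numeric matrix of Gaussian centers (rows), in standardized
#'   coordinates when \code{standardize = TRUE} at training time.
#' @slot spread numeric Gaussian width; activation is
#'   \eqn{\exp(-\|x - c\|^2 / (2\,spread^2))}.
#' @slot weights numeric (nCenters + 1) x 2 output weight matrix, first row
#'   is the bias.
#' @slot mseTrajectory numeric vector of training MSE, starting at the
#'   bias-only (0 neuron) solution and appended after every added neuron;
#'   non-increasing by construction.
#' @slot center,scale numeric vectors used to standardize inputs (length 0
#'   when standardization is off).
#' @slot classLevels character(2); the second entry is the positive class.
#' @export
setClass("RBFNNModel",
         representation(centers = "matrix", spread = "numeric",
                        weights = "matrix", mseTrajectory = "numeric",
                        center = "numeric", scale = "numeric",
                        classLevels = "character"))

#' @rdname accessors
#' @export
setMethod("mseTrajectory", "RBFNNModel", function(x) x@mseTrajectory)

#' @rdname accessors
#' @export
setMethod("rbfCenters", "RBFNNModel", function(x) x@centers)

## ---------------------------------------------------------------------------
## CVResult
## ---------------------------------------------------------------------------

#' Stratified k-fold cross-validation result
#'
#' Pooled out-of-fold predictions: every sample appears in exactly one test
#' fold, so the pooled confusion counts sum to the number of samples.
#'
#' @slot folds integer vector of fold assignments (1..nFolds).
#' @slot labels factor of true labels.
#' @slot predictions factor of pooled out-of-fold predictions.
#' @slot scores numeric pooled class-1 scores (for AUC).
#' @slot outputs two-column matrix of raw model outputs (RBFNN) or NULL.
#' @slot perFold list of per-fold records (test indices, selected features,
#'   hidden-neuron counts where applicable).
#' @slot model character, \code{"knn"} or \code{"rbfnn"}.
#' @slot seed integer seed that generated the folds.
#' @export
setClass("CVResult",
         representation(folds = "integer", labels = "factor",
                        predictions = "factor", scores = "numeric",
                        outputs = "ANY", perFold = "list",
                        model = "character", seed = "integer"))

setValidity("CVResult", function(object) {
  n <- length(object@labels)
  if (length(object@folds) != n || length(object@predictions) != n ||
      length(object@scores) != n)
    return("folds, predictions and scores must match the number of samples")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("foldAssignments", "CVResult", function(x) x@folds)

#' @rdname accessors
#' @export
setMethod("pooledPredictions", "CVResult", function(x) x@predictions)

#' @rdname accessors
#' @export
setMethod("pooledScores", "CVResult", function(x) x@scores)

## ---------------------------------------------------------------------------
## EvalMetrics
## ---------------------------------------------------------------------------

#' Confusion-matrix metric suite
#'
#' Melanoma (the second factor level) is the positive class. Undefined ratios
#' (zero denominators) are reported as \code{NA} with a warning, never as 0.
#'
#' @slot tp,fp,fn,tn integer confusion counts.
#' @slot sensitivity,accuracy,precision numeric in \code{[0, 1]}.
#' @slot auc numeric Mann-Whitney rank AUC over scores (NA without scores).
#' @slot dice numeric Dice score \eqn{2TP/(2TP+FP+FN)}.
#' @slot mse numeric mean squared error of model outputs against one-hot
#'   targets (NA when no outputs/scores are supplied).
#' @slot mseComparable logical; FALSE when mse was computed from surrogate
#'   scores (e.g. kNN neighbor fractions) rather than network outputs.
#' @export
setClass("EvalMetrics",
         representation(tp = "integer", fp = "integer", fn = "integer",
                        tn = "integer", sensitivity = "numeric",
                        accuracy = "numeric", precision = "numeric",
                        auc = "numeric", dice = "numeric", mse = "numeric",
                        mseComparable = "logical"))
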