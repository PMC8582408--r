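#' @import methods
NULL

#' Accessor generics
#'
#' Small family of accessors for the S4 containers used across the package.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot content documented with each class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterBoxes", function(x) standardGeneric("clusterBoxes"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("meanHFD", function(x) standardGeneric("meanHFD"))

#' @rdname accessors
#' @export
setGeneric("hfdChannels", function(x) standardGeneric("hfdChannels"))

#' @rdname accessors
#' @export
setGeneric("surfaceGrid", function(x) standardGeneric("surfaceGrid"))

#' @rdname accessors
#' @export
setGeneric("hurst", function(x) standardGeneric("hurst"))

#' @rdname accessors
#' @export
setGeneric("theoreticalFD", function(x) standardGeneric("theoreticalFD"))

#' @rdname accessors
#' @export
setGeneric("lesionImage", function(x) standardGeneric("lesionImage"))

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))

#' @rdname accessors
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("mseTrajectory", function(x) standardGeneric("mseTrajectory"))

#' @rdname accessors
#' @export
setGeneric("rbfCenters", function(x) standardGeneric("rbfCenters"))

#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname accessors
#' @export
setGeneric("pooledPredictions", function(x) standardGeneric("pooledPredictions"))

#' @rdname accessors
#' @export
setGeneric("pooledScores", function(x) standardGeneric("pooledScores"))
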