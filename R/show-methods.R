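#' @describeIn ColorClusterSet compact display.
#' @param object a \code{ColorClusterSet}.
#' @export
setMethod("show", "ColorClusterSet", function(object) {
  cat("ColorClusterSet with", nClusters(object), "boxes:",
      paste(utils::head(clusterIds(object), 6L), collapse = ", "),
      if (nClusters(object) > 6L) "..." else "", "\n")
})

#' @describeIn LesionFeatureSet compact display.
#' @param object a \code{LesionFeatureSet}.
#' @export
setMethod("show", "LesionFeatureSet", function(object) {
  cat(class(object), "with", nrow(object@features), "samples x",
      ncol(object@features), "features\n")
  print(table(object@labels))
})

#' @describeIn FBMSurface compact display.
#' @param object an \code{FBMSurface}.
#' @export
setMethod("show", "FBMSurface", function(object) {
  cat(sprintf("FBMSurface %dx%d, hurst = %.2f (theoretical FD %.2f), seed %d\n",
              nrow(object@grid), ncol(object@grid), object@hurst,
              3 - object@hurst, object@seed))
})

#' @describeIn SyntheticLesion compact display.
#' @param object a \code{SyntheticLesion}.
#' @export
setMethod("show", "SyntheticLesion", function(object) {
  cat(sprintf("SyntheticLesion %dx%d, mask area %d px\n",
              dim(object@image)[1], dim(object@image)[2], sum(object@mask)))
  comp <- paste(sprintf("%s: %.3f", names(object@composition),
                        object@composition), collapse = ", ")
  cat(" composition:", comp, "\n")
})

#' @describeIn HFDResult compact display.
#' @param object an \code{HFDResult}.
#' @export
setMethod("show", "HFDResult", function(object) {
  h <- vapply(object@channels, `[[`, numeric(1), "hfd")
  cat(sprintf("HFDResult (kMax = %d, %s): R %.4f  G %.4f  B %.4f\n",
              object@config@kMax, object@config@formulaMode,
              h[1], h[2], h[3]))
  cat(sprintf(" mean HFD = %.4f (clamped to [2,3]: %.4f)\n",
              object@meanHFD, object@meanHFDClamped))
})

#' @describeIn SelectionResult compact display.
#' @param object a \code{SelectionResult}.
#' @export
setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d / %d features selected at p < %g\n",
              sum(object@table$selected), nrow(object@table), object@alpha))
})

#' @describeIn RBFNNModel compact display.
#' @param object an \code{RBFNNModel}.
#' @export
setMethod("show", "RBFNNModel", function(object) {
  cat(sprintf(paste0("RBFNNModel: %d Gaussian centers, spread %.4g, ",
                     "final training MSE %.4g\n"),
              nrow(object@centers), object@spread,
              utils::tail(object@mseTrajectory, 1L)))
})

#' @describeIn CVResult compact display.
#' @param object a \code{CVResult}.
#' @export
setMethod("show", "CVResult", function(object) {
  m <- pooledMetrics(object)
  cat(sprintf("CVResult (%s, %d folds, seed %d): pooled accuracy %.2f%%\n",
              object@model, max(object@folds), object@seed,
              100 * m@accuracy))
})

#' @describeIn EvalMetrics compact display.
#' @param object an \code{EvalMetrics}.
#' @export
setMethod("show", "EvalMetrics", function(object) {
  cat(sprintf("EvalMetrics: tp %d fp %d fn %d tn %d\n",
              object@tp, object@fp, object@fn, object@tn))
  cat(sprintf(" sensitivity %.4f  accuracy %.4f  precision %.4f\n",
              object@sensitivity, object@accuracy, object@precision))
  cat(sprintf(" AUC %.4f  Dice %.4f  MSE %.4g%s\n", object@auc, object@dice,
              object@mse,
              if (!object@mseComparable && !is.na(object@mse))
                " (score-based, not comparable to network MSE)" else ""))
})
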