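#' Feature selection by per-feature two-sample t-test
#'
#' Runs a Welch (unequal-variance) two-sample t-test on every feature column
#' and keeps features with strictly \code{p < alpha}. Welch's variant is used
#' because the lesion datasets this targets are strongly class-imbalanced.
#' Features with zero variance in both groups carry no information: they are
#' flagged, their p-value is reported as \code{NA}, and they are never
#' selected. No multiple-testing correction is applied by default (plain
#' \code{p < 0.05} rule); \code{adjust} exposes [stats::p.adjust()] methods
#' for stricter workflows.
#'
#' @param x a [LesionFeatureSet-class], or a numeric samples-by-features
#'   matrix if \code{labels} is given.
#' @param labels two-class factor (ignored when \code{x} is a feature set).
#' @param alpha significance threshold (default 0.05, strict inequality).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default \code{"none"}.
#' @return A [SelectionResult-class]; its table retains every feature with its
#'   t statistic and p-value.
#' @examples
#' tab <- twoClassTable(30, nInformative = 2, nNoise = 4, effect = 2, seed = 1)
#' sel <- ttestSelect(tab)
#' selectedFeatures(sel)
#' @export
ttestSelect <- function(x, labels = NULL, alpha = 0.05, adjust = "none") {
  if (is(x, "LesionFeatureSet")) {
    labels <- sampleLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("selection needs exactly two classes in the labels")
  if (min(table(labels)) < 2L)
    stop("selection needs at least 2 samples per class")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  g1 <- labels == levels(labels)[1]
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(x)))
  tstat <- pval <- rep(NA_real_, ncol(x))
  flagged <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    a <- x[g1, j]
    b <- x[!g1, j]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      flagged[j] <- TRUE
      next
    }
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      flagged[j] <- TRUE
    } else {
      tstat[j] <- unname(tt$statistic)
      pval[j] <- tt$p.value
    }
  }
  padj <- if (identical(adjust, "none")) pval else stats::p.adjust(pval, adjust)
  selected <- !is.na(padj) & padj < alpha
  new("SelectionResult",
      table = data.frame(feature = feats, t = tstat, p = pval,
                         selected = selected, flagged = flagged,
                         stringsAsFactors = FALSE),
      alpha = alpha)
}

#' Write a selection report to CSV
#'
#' @param selection a [SelectionResult-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSelectionReport <- function(selection, path) {
  stopifnot(is(selection, "SelectionResult"))
  utils::write.csv(selectionTable(selection), path, row.names = FALSE)
  invisible(path)
}
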