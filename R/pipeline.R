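## End-to-end orchestration: manifest -> preprocessing -> color + HFD
## features -> t-test selection -> classifier under stratified 5-fold CV ->
## report bundle.

#' Read an image manifest
#'
#' CSV with columns \code{image_path}, \code{label} (\code{nevus} or
#' \code{melanoma}) and optionally \code{mask_path} and \code{dataset_tag}.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with normalized columns.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "label") %in% colnames(m)))
    stop("manifest needs at least columns image_path and label")
  if (!"mask_path" %in% colnames(m)) m$mask_path <- NA_character_
  if (!"dataset_tag" %in% colnames(m)) m$dataset_tag <- "dataset"
  bad <- !m$label %in% c("nevus", "melanoma")
  if (any(bad))
    stop("labels must be 'nevus' or 'melanoma'; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                            p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  m
}

#' Pipeline configuration
#'
#' Validated bundle of all pipeline settings; validation happens before any
#' image is read.
#'
#' @param clusters a [ColorClusterSet-class] or path to a cluster config file
#'   (default: the packaged 23-cluster set).
#' @param hfd an [HFDConfig-class].
#' @param alpha t-test selection threshold.
#' @param model \code{"knn"} or \code{"rbfnn"}.
#' @param folds,seed cross-validation controls.
#' @param k,maxNeurons,mseGoal,spread,standardize classifier controls.
#' @param hairRemoval run [removeHair()] on every image (default FALSE; the
#'   synthetic fixtures are hair-free).
#' @param lineStrength hair-detection threshold, see [removeHair()].
#' @param paperFaithful when TRUE, feature selection is run once globally
#'   before cross-validation (the order described in the source methodology,
#'   which leaks test information into selection — a warning is logged);
#'   when FALSE (default) selection is refit inside every training fold.
#' @param outputDir optional directory for the report bundle written by
#'   [runPipeline()].
#' @return a validated configuration (list).
#' @export
pipelineConfig <- function(clusters = defaultClusterSet(), hfd = hfdConfig(),
                           alpha = 0.05, model = c("rbfnn", "knn"),
                           folds = 5L, seed = 1L, k = 5L, maxNeurons = 50L,
                           mseGoal = 0.01, spread = NULL, standardize = TRUE,
                           hairRemoval = FALSE, lineStrength = 20,
                           paperFaithful = FALSE, outputDir = NULL) {
  if (is.character(clusters)) clusters <- loadClusterSet(clusters)
  stopifnot(is(clusters, "ColorClusterSet"), is(hfd, "HFDConfig"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(clusters = clusters, hfd = hfd, alpha = alpha,
                 model = match.arg(model), folds = as.integer(folds),
                 seed = as.integer(seed), k = as.integer(k),
                 maxNeurons = as.integer(maxNeurons), mseGoal = mseGoal,
                 spread = spread, standardize = standardize,
                 hairRemoval = hairRemoval, lineStrength = lineStrength,
                 paperFaithful = paperFaithful, outputDir = outputDir),
            class = "PipelineConfig")
}

#' Extract color-cluster and HFD features for a manifest
#'
#' Per image: optional hair removal, mask acquisition (the manifest's mask if
#' provided, otherwise [segmentLesion()]), color-cluster percentages within
#' the mask, and the whole-image mean HFD. Per-image failures are logged as
#' warnings and the run continues; failed rows are excluded and counted.
#'
#' @param manifest data.frame from [readManifest()] (or of the same shape).
#' @param config a [pipelineConfig()].
#' @return list with \code{features} (a [LesionFeatureSet-class] whose columns
#'   are the cluster ids plus \code{hfd}), \code{table} (per-image data.frame
#'   including the \code{unassigned} percentage), \code{nFailed} and
#'   \code{failed} (paths of skipped rows).
#' @export
extractFeatures <- function(manifest, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  ids <- clusterIds(config$clusters)
  rows <- vector("list", nrow(manifest))
  failed <- character(0)
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch({
      img <- readRGBImage(manifest$image_path[i])
      if (isTRUE(config$hairRemoval))
        img <- removeHair(img, lineStrength = config$lineStrength)
      mask <- if (!is.na(manifest$mask_path[i]) &&
                  nzchar(manifest$mask_path[i])) {
        readMask(manifest$mask_path[i])
      } else {
        segmentLesion(img)
      }
      pct <- clusterPercentages(img, mask, config$clusters)
      hfd <- meanHFD(imageHFD(img, config$hfd))
      c(pct[ids], hfd = hfd, unassigned = unname(pct["unassigned"]))
    }, error = function(e) {
      warning("skipping ", manifest$image_path[i], ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    rows[[i]] <- rec
    if (is.null(rec)) failed <- c(failed, manifest$image_path[i])
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("pipeline error: feature extraction failed for all ",
                     nrow(manifest), " images")
  values <- do.call(rbind, rows[ok])
  features <- values[, c(ids, "hfd"), drop = FALSE]
  fs <- LesionFeatureSet(features, manifest$label[ok])
  tab <- data.frame(image_path = manifest$image_path[ok],
                    label = manifest$label[ok],
                    dataset_tag = manifest$dataset_tag[ok],
                    values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  list(features = fs, table = tab, nFailed = sum(!ok), failed = failed)
}

#' Run the full classification pipeline
#'
#' Feature extraction, t-test selection, cross-validated classification and
#' reporting. By default selection is refit inside each training fold so no
#' test-fold information influences it; \code{paperFaithful = TRUE} instead
#' selects once on all data before cross-validation (with a logged leakage
#' warning). When \code{config$outputDir} is set, the bundle (features CSV,
#' selection report, CV report, serialized model, run log) is written there.
#'
#' @param manifest data.frame from [readManifest()].
#' @param config a [pipelineConfig()].
#' @return list with \code{features}, \code{extraction}, \code{selection}
#'   (global report), \code{cv} (a [CVResult-class]), \code{report}
#'   (data.frame), \code{model} (fit on all data) and \code{paths} of any
#'   files written.
#' @export
runPipeline <- function(manifest, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  ex <- extractFeatures(manifest, config)
  fs <- ex$features
  sel <- ttestSelect(fs, alpha = config$alpha)

  if (config$paperFaithful) {
    warning("paperFaithful selection order: features selected on all data ",
            "before cross-validation (test-fold leakage into selection)")
    keep <- selectedFeatures(sel)
    if (length(keep) == 0L) keep <- colnames(featureMatrix(fs))
    x <- featureMatrix(fs)[, keep, drop = FALSE]
    cv <- runCV(x, sampleLabels(fs), model = config$model,
                folds = config$folds, seed = config$seed, k = config$k,
                maxNeurons = config$maxNeurons, mseGoal = config$mseGoal,
                spread = config$spread, standardize = config$standardize,
                selectWithin = FALSE)
  } else {
    cv <- runCV(fs, model = config$model, folds = config$folds,
                seed = config$seed, k = config$k,
                maxNeurons = config$maxNeurons, mseGoal = config$mseGoal,
                spread = config$spread, standardize = config$standardize,
                selectWithin = TRUE, alpha = config$alpha)
  }
  dataset <- if (nrow(ex$table) > 0L) ex$table$dataset_tag[1] else "dataset"
  report <- renderReport(cv, datasetName = dataset)

  finalModel <- NULL
  if (config$model == "rbfnn") {
    keep <- selectedFeatures(sel)
    if (length(keep) == 0L) keep <- colnames(featureMatrix(fs))
    finalModel <- trainRBFNN(featureMatrix(fs)[, keep, drop = FALSE],
                             sampleLabels(fs), maxNeurons = config$maxNeurons,
                             mseGoal = config$mseGoal, spread = config$spread,
                             standardize = config$standardize)
  }

  paths <- character(0)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    fts <- file.path(config$outputDir, "features.csv")
    utils::write.csv(ex$table, fts, row.names = FALSE)
    selp <- file.path(config$outputDir, "selection.csv")
    writeSelectionReport(sel, selp)
    repp <- file.path(config$outputDir, "cv_report.csv")
    utils::write.csv(report, repp, row.names = FALSE)
    paths <- c(features = fts, selection = selp, report = repp)
    if (!is.null(finalModel)) {
      mp <- file.path(config$outputDir, "rbfnn_model.json")
      writeRBFNN(finalModel, mp)
      paths <- c(paths, model = mp)
    }
    logp <- file.path(config$outputDir, "run_log.json")
    jsonlite::write_json(
      list(seed = config$seed, folds = config$folds, model = config$model,
           alpha = config$alpha, standardize = config$standardize,
           selectionMode = if (config$paperFaithful) "global_pre_cv"
                           else "within_fold",
           kMax = config$hfd@kMax, formulaMode = config$hfd@formulaMode,
           fitScale = config$hfd@fitScale,
           nImages = nrow(manifest), nFailed = ex$nFailed,
           failed = ex$failed),
      logp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, log = logp)
  }
  list(features = fs, extraction = ex, selection = sel, cv = cv,
       report = report, model = finalModel, paths = paths)
}
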