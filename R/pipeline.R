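#' Pipeline run configuration
#'
#' All tunable parameters of the end-to-end pipeline with their documented
#' defaults: 9 s windows with 4.5 s overlap, the arc-cosine angle convention,
#' a 45 deg binarization threshold, weighted spectral features,
#' standardized PCA, deterministic GMM (seed recorded), a 0.5 subject
#' decision threshold, and a fixed 1e-5 edgewise significance threshold.
#'
#' @param windowS,overlapS segmentation window and overlap in seconds.
#' @param convention angle convention (\code{"distance"} or
#'   \code{"literal"}).
#' @param center subtract channel window means before the angle computation.
#' @param absolute fold angles into [0, 90].
#' @param threshold binarization threshold in degrees.
#' @param richClubK rich-club degree threshold (NULL = floor(nn/2)).
#' @param spectralMode adjacency for spectral features.
#' @param weightTransform weight transform for spectral features.
#' @param standardize z-score features before the SVD.
#' @param gmmSeed,gmmTol,gmmMaxIter GMM fitting controls.
#' @param subjectThreshold probability threshold for the binary call.
#' @param alphaAdj edgewise significance threshold on raw p-values.
#' @return list of class \code{"epiFCNConfig"}.
#' @export
runConfig <- function(windowS = 9, overlapS = 4.5,
                      convention = c("distance", "literal"),
                      center = FALSE, absolute = FALSE,
                      threshold = 45, richClubK = NULL,
                      spectralMode = c("weighted", "binary"),
                      weightTransform = c("degrees", "radians", "cosine"),
                      standardize = TRUE,
                      gmmSeed = 1L, gmmTol = 1e-8, gmmMaxIter = 500L,
                      subjectThreshold = 0.5, alphaAdj = 1e-5) {
  structure(list(
    windowS = windowS, overlapS = overlapS,
    convention = match.arg(convention),
    center = center, absolute = absolute,
    threshold = threshold, richClubK = richClubK,
    spectralMode = match.arg(spectralMode),
    weightTransform = match.arg(weightTransform),
    standardize = standardize,
    gmmSeed = as.integer(gmmSeed), gmmTol = gmmTol,
    gmmMaxIter = as.integer(gmmMaxIter),
    subjectThreshold = subjectThreshold, alphaAdj = alphaAdj),
    class = "epiFCNConfig")
}

#' Write a flat key-value echo of a run configuration
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfigEcho <- function(cfg, path) {
  kv <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k, if (is.null(v)) "default" else format(v))
  }, "")
  writeLines(kv, path)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Chains every stage: segmentation, connectivity network construction,
#' graph-feature extraction, PCA, unsupervised two-component Gaussian
#' mixture labelling, clinical identification of the components via mean
#' connectivity angle, per-subject probability, and the binary call. When
#' ground-truth groups are available (from the recordings or a truth table),
#' confusion metrics are computed too.
#'
#' @param recordings list of \linkS4class{EEGRecording}, or a character
#'   vector of file paths readable by \code{\link{readRecording}}.
#' @param truth optional data.frame with subject_id and group columns; when
#'   NULL, group labels carried by the recordings are used if informative.
#' @param config a \code{\link{runConfig}}.
#' @param outputDir optional directory; when given, the subject report,
#'   feature table, model dump and a config echo are written there.
#' @return list with \code{report} (subject table with calls),
#'   \code{features} (SummarizedExperiment), \code{model}
#'   (\linkS4class{GaussianMixture2}), \code{scores}, \code{segmentLabels},
#'   \code{confusion} (or NULL), and \code{config}.
#' @export
runPipeline <- function(recordings, truth = NULL, config = runConfig(),
                        outputDir = NULL) {
  if (is.character(recordings)) {
    if (!length(recordings)) stop("usage error: empty input list")
    recordings <- lapply(recordings, readRecording)
  }
  if (!length(recordings)) stop("usage error: empty input list")
  segments <- list()
  for (rec in recordings) {
    segs <- segmentRecording(rec, windowS = config$windowS,
                             overlapS = config$overlapS)
    segments <- c(segments, segs)
  }
  if (length(segments) < 4)
    stop("insufficient segments for unsupervised labelling: got ",
         length(segments), ", need at least 4")
  message("epiFCN: ", length(segments), " segments from ",
          length(recordings), " recording(s)")
  fcns <- lapply(segments, buildFCN, convention = config$convention,
                 center = config$center, absolute = config$absolute)
  cfg <- featureConfig(threshold = config$threshold,
                       richClubK = config$richClubK,
                       spectralMode = config$spectralMode,
                       weightTransform = config$weightTransform)
  se <- featureMatrix(fcns, cfg)
  pc <- withCallingHandlers(
    firstPC(se, standardize = config$standardize),
    warning = function(w) {
      message("epiFCN: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  model <- fitGMM(pc$scores, seed = config$gmmSeed, tol = config$gmmTol,
                  maxIter = config$gmmMaxIter)
  comp <- labelSegments(model, pc$scores)
  classes <- mapComponentsToClasses(
    comp, SummarizedExperiment::colData(se)$mean_angle)
  report <- subjectProbability(
    SummarizedExperiment::colData(se)$subject_id, classes)
  report <- classifySubject(report, threshold = config$subjectThreshold)
  confusion <- NULL
  truthMap <- NULL
  if (!is.null(truth)) {
    truthMap <- stats::setNames(truth$group, truth$subject_id)
  } else {
    g <- vapply(recordings, groupLabel, "")
    if (all(g %in% c("control", "epilepsy")))
      truthMap <- stats::setNames(g, vapply(recordings, subjectID, ""))
  }
  if (!is.null(truthMap)) {
    tr <- truthMap[report$subject_id]
    if (!anyNA(tr) && length(unique(tr)) == 2)
      confusion <- confusionMetrics(report$call, tr)
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSubjectReports(report, file.path(outputDir, "subject_report.tsv"))
    writeFeatureTable(se, file.path(outputDir, "feature_table.tsv"))
    writeModelDump(model, file.path(outputDir, "model.txt"))
    writeConfigEcho(config, file.path(outputDir, "config_echo.txt"))
    if (!is.null(confusion))
      utils::write.table(
        data.frame(metric = names(confusion), value = unname(confusion)),
        file.path(outputDir, "confusion_metrics.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, features = se, model = model, scores = pc$scores,
       loadings = pc$loadings, segmentLabels = classes,
       confusion = confusion, config = config)
}
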