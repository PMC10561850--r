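#' Default experiment configuration
#'
#' Returns the configuration reproducing the reference analysis settings:
#' training fraction 39/64, \code{k = 25} selected features, classes 1 and 2
#' merged, normalization constants \eqn{\alpha = 2, \beta = 1}, margin-mode
#' scoring, pairwise voting, threshold calibration on the training samples,
#' and evaluation over all samples.  Any field can be overridden.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of configuration fields.
#' @export
experimentConfig <- function(...) {
  cfg <- list(
    input = NULL,               # CSV path; NULL -> synthetic data
    synthetic = list(),         # overrides for simulateExpression()
    trainFraction = 39 / 64,
    seed = 0L,
    alpha = 2, beta = 1, fitOn = "train",
    k = 25, scoreMode = "margin",
    mergeSet = c(1, 2), mergeLabel = NULL,
    classifyMode = "vote",      # "vote" or "tree"
    tree = NULL,                # decision nodes; NULL -> greedy build
    calibrateOn = "train",      # "train" or "all"
    evalOn = "all",             # "all" or "test"
    tol = 1e-6,
    outputDir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full classification experiment
#'
#' Orchestrates the stages load/simulate, merge, stratified split, min-max
#' normalization, margin feature selection, pairwise LP plane fitting,
#' threshold calibration, classification and evaluation, as one
#' reproducible seeded run.  When \code{config$outputDir} is set, the split
#' CSVs, feature table, plane table, predictions, evaluation report and a
#' run manifest are written there; the whole run is reproducible from the
#' manifest.
#'
#' @param config list from [experimentConfig()].
#' @return List with elements \code{split}, \code{features},
#'   \code{planes}, \code{calibrated}, \code{predictions}, \code{report}
#'   (confusion matrix, metrics under both rounding modes, pairwise
#'   precision tables) and \code{manifest}.
#' @export
runExperiment <- function(config = experimentConfig()) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  data <- stage("load", {
    if (is.null(config$input)) {
      do.call(simulateExpression,
              utils::modifyList(list(seed = config$seed), config$synthetic))
    } else readCumidaCsv(config$input)
  })
  if (!is.null(config$mergeSet))
    data <- stage("merge", mergeClasses(data, config$mergeSet,
                                        config$mergeLabel))

  split <- stage("split",
    stratifiedSplit(data, config$trainFraction, config$seed))
  train <- split@train; test <- split@test

  params <- stage("normalize", fitMinmax(
    if (identical(config$fitOn, "all")) data else train,
    alpha = config$alpha, beta = config$beta, fittedOn = config$fitOn))
  zTrain <- transformMinmax(train, params)
  zAll <- transformMinmax(data, params)

  features <- stage("select", {
    cc <- centerByClass(zTrain, classCodes(train), classSet(train))
    sc <- scoreFeatures(cc, zTrain, classCodes(train), mode = config$scoreMode)
    selectTopK(sc, k = config$k, probeIds = probeIds(train))
  })

  nTrain <- restrictFeatures(setExpressionValues(train, zTrain), features)
  nAll <- restrictFeatures(setExpressionValues(data, zAll), features)
  nEval <- if (identical(config$evalOn, "test")) {
    zTest <- transformMinmax(test, params)
    restrictFeatures(setExpressionValues(test, zTest), features)
  } else nAll

  planes <- stage("fit", fitAllPairs(nTrain, tol = config$tol))
  calibrated <- stage("calibrate", calibrateAllPlanes(
    planes, if (identical(config$calibrateOn, "all")) nAll else nTrain))

  predictions <- stage("predict", {
    if (identical(config$classifyMode, "tree")) {
      nodes <- if (is.null(config$tree))
        greedyDecisionList(calibrated, nTrain) else config$tree
      classifyDecisionList(nEval, nodes, calibrated)
    } else classifyVote(nEval, calibrated,
                        nClasses = length(classSet(data)))
  })

  report <- stage("evaluate", {
    groups <- classSet(data)
    cm <- confusionCounts(classLabels(nEval), groups[predictions], groups)
    list(confusion = cm,
         metricsExact = classificationMetrics(cm, "exact"),
         metricsPaper = classificationMetrics(cm, "paper"),
         pairwise = pairwisePrecision(nEval, calibrated),
         trainingAccuracy = 100 * mean(
           classifyVote(nTrain, calibrated,
                        nClasses = length(classSet(data))) ==
             classCodes(train)))
  })

  manifest <- list(config = config[setdiff(names(config), "tree")],
                   package = as.character(utils::packageVersion("lpgx")),
                   rVersion = R.version.string)
  result <- list(split = split, features = features, planes = planes,
                 calibrated = calibrated, predictions = predictions,
                 report = report, manifest = manifest)
  if (!is.null(config$outputDir))
    .writeArtifacts(result, data, config)
  result
}

.writeArtifacts <- function(result, data, config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  writeCumidaCsv(result$split@train, out("train.csv"))
  writeCumidaCsv(result$split@test, out("test.csv"))
  feats <- result$features
  utils::write.table(
    data.frame(rank = seq_len(feats@k), feature_no = feats@indices,
               probe_set_id = feats@probeIds),
    out("features.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  planeTab <- do.call(rbind, lapply(result$planes, function(p)
    data.frame(class_i = p@pair[1], class_j = p@pair[2],
               objective = p@objectiveValue, separable = p@separable,
               b = p@bias, t(p@weights))))
  utils::write.table(planeTab, out("planes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  evalIds <- if (identical(config$evalOn, "test"))
    sampleIds(result$split@test) else sampleIds(data)
  utils::write.table(
    data.frame(sample = evalIds,
               predicted = classSet(data)[result$predictions]),
    out("predictions.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  rep <- result$report
  jsonlite::write_json(list(
    confusion = rep$confusion,
    metrics_exact = rep$metricsExact, metrics_paper = rep$metricsPaper,
    pairwise = rep$pairwise, training_accuracy = rep$trainingAccuracy),
    out("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
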