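#' Pipeline run configuration
#'
#' Collects every stage's parameters with the package defaults, a
#' master seed, and stage toggles. The whole run is a pure function of
#' this configuration.
#'
#' @param seed master RNG seed (drives simulation and fold assignment).
#' @param nPerClass animals per phenotype class.
#' @param stages named logical vector enabling `simulate`, `extract`,
#'   `select`, `classify`, `cluster`.
#' @param quantization [quantizationParams()].
#' @param denoise [denoiseParams()] or `NULL`.
#' @param rMax signature correlation threshold.
#' @param folds cross-validation folds.
#' @param nClusters clusters for the unsupervised analysis.
#' @param ... overrides forwarded to [generateStudy()] (e.g.
#'   `imageSize`, `speckleScale`).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L,
                           nPerClass = c(P1 = 5L, P2 = 5L, P3 = 4L),
                           stages = c(simulate = TRUE, extract = TRUE,
                                      select = TRUE, classify = TRUE,
                                      cluster = TRUE),
                           quantization = quantizationParams(),
                           denoise = denoiseParams(), rMax = 0.75,
                           folds = 4L, nClusters = 3L, ...) {
  structure(list(seed = as.integer(seed), nPerClass = nPerClass,
                 stages = stages, quantization = quantization,
                 denoise = denoise, rMax = rMax, folds = as.integer(folds),
                 nClusters = as.integer(nClusters),
                 studyArgs = list(...)),
            class = "PipelineConfig")
}

#' Run the full radiomics pipeline
#'
#' Executes the enabled stages in order: synthetic study generation,
#' feature extraction (235 features per scan/user/dataset), signature
#' selection by the four-criterion ranking, supervised classification
#' (linear SVM, stratified k-fold cross-validation, Wilson interval)
#' on the signature, and unsupervised clustering of all features with
#' enrichment testing. Supervised and unsupervised analyses use the
#' user-1/dataset-1 sample of each scan.
#'
#' @param config a [pipelineConfig()] object.
#' @param study optionally, a pre-built [CEUSStudy-class] (used when
#'   the simulate stage is disabled).
#' @param features optionally, a pre-built [RadiomicFeatureSet-class].
#' @param verbose print stage progress.
#' @return a named list report: the study, feature set, ranking table,
#'   signature, classification and clustering results of the enabled
#'   stages, plus the resolved configuration.
#' @export
runPipeline <- function(config = pipelineConfig(), study = NULL,
                        features = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  report <- list(config = config)
  on <- function(s) isTRUE(config$stages[[s]])
  if (on("simulate")) {
    say("simulate: generating synthetic study")
    study <- do.call(generateStudy,
                     c(list(nPerClass = config$nPerClass,
                            seed = config$seed), config$studyArgs))
  }
  report$study <- study
  if (on("extract")) {
    if (is.null(study)) stop("extract stage needs a study")
    say("extract: building the feature table")
    features <- buildFeatureTable(study, q = config$quantization,
                                  denoise = config$denoise,
                                  verbose = verbose)
  }
  report$features <- features
  if (!is.null(features))
    report$featureCounts <- table(featureClasses(features))
  signature <- NULL
  if (on("select")) {
    if (is.null(features)) stop("select stage needs features")
    say("select: ranking features and pruning the signature")
    ranking <- rankFeatures(features)
    signature <- selectSignature(
      ranking, featureMatrix(features, "user1", "1"), rMax = config$rMax)
    report$ranking <- ranking
    report$signature <- signature
  }
  cd <- if (!is.null(features)) SummarizedExperiment::colData(features)
  if (on("classify")) {
    if (is.null(signature)) stop("classify stage needs a signature")
    say("classify: cross-validated linear SVM")
    vals <- featureMatrix(features, "user1", "1")
    labs <- scanLabels(features)
    z <- zscoreTable(vals[, signatureFeatures(signature), drop = FALSE])
    cv <- cvSVM(z, labs, k = config$folds, seed = config$seed)
    report$classification <- cv
    report$accuracy <- accuracy(cv)
    report$wilsonCI <- wilsonCI(cv)
  }
  if (on("cluster")) {
    if (is.null(features)) stop("cluster stage needs features")
    say("cluster: average-linkage clustering and enrichment")
    vals <- featureMatrix(features, "user1", "1")
    labs <- scanLabels(features)
    cl <- hierarchicalCluster(zscoreTable(vals), config$nClusters)
    cl@enrichment <- clusterEnrichment(clusterLabels(cl), labs)
    report$clustering <- cl
  }
  report
}

# model label per scan, aligned with featureMatrix's row order
scanLabels <- function(features, userID = "user1", datasetID = "1") {
  cd <- SummarizedExperiment::colData(features)
  keep <- cd$userID == userID & cd$datasetID == datasetID
  sub <- cd[keep, ]
  sub$modelLabel[order(sub$scanID)]
}
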