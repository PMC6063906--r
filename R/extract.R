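featureClassOf <- function(featureNames) {
  ifelse(grepl("^wavelet", featureNames), "wavelet",
         ifelse(grepl("^vascular", featureNames), "vascular",
                ifelse(grepl("^firstorder", featureNames), "first_order",
                       "textural")))
}

#' Extract the full 235-feature radiomic vector from one scan
#'
#' Orchestrates the per-scan analysis: the sequence is speckle-denoised
#' ([denoiseSequence()]); intensity, texture and wavelet features are
#' computed on the reference B-mode image (the per-pixel temporal mean
#' of the denoised pre-destruction frames); the vasculature is
#' segmented ([segmentVessels()]) and the replenishment kinetics fitted
#' ([fitReplenishment()]) to supply the 15 vascular features. The
#' result has exactly 235 entries: 14 first-order, 30 textural, 15
#' vascular and 176 wavelet features.
#'
#' @param seq a [CEUSSequence-class].
#' @param roi an [ROIMask-class].
#' @param q [quantizationParams()].
#' @param denoise a [denoiseParams()] object, or `NULL` to skip
#'   denoising (e.g. when the input is already filtered).
#' @param beamWidth velocity calibration constant.
#' @return named numeric vector of 235 features with attribute
#'   `featureClass`.
#' @export
extractFeatures <- function(seq, roi, q = quantizationParams(),
                            denoise = denoiseParams(), beamWidth = 1) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("feature extraction failed at stage '", what, "': ",
           conditionMessage(e), call. = FALSE))
  }
  den <- stage("denoise", if (is.null(denoise)) seq else
    denoiseSequence(seq, denoise))
  fd <- den@destructionFrame
  ref <- stage("reference frame", {
    pre <- den@frames[, , seq_len(fd - 1L), drop = FALSE]
    apply(pre, c(1, 2), mean)
  })
  fo <- stage("first-order", firstOrderFeatures(ref, roi, q))
  tex <- stage("texture", texturalFeatures(ref, roi, q))
  wav <- stage("wavelet", waveletSubbandFeatures(ref, roi, q))
  vessel <- stage("segmentation", segmentVessels(den, roi))
  fit <- stage("replenishment fit",
               fitReplenishment(den, roi, excluded = vessel@excludedFrames,
                                beamWidth = beamWidth))
  vasc <- stage("vascular", vascularFeatures(vessel, roi, fit))
  out <- c(fo, tex, vasc, wav)
  stopifnot(length(out) == 235L, all(is.finite(out)))
  attr(out, "featureClass") <- featureClassOf(names(out))
  out
}

# per-sequence cached intermediates shared across the three users:
# denoised stack, wiener-smoothed stack, artifact frames, unmasked
# difference MIP
prepareSequence <- function(seq, denoise = denoiseParams()) {
  den <- if (is.null(denoise)) seq else denoiseSequence(seq, denoise)
  sm <- den
  for (t in seq_len(dim(den@frames)[3]))
    sm@frames[, , t] <- adaptiveSmooth(den@frames[, , t])
  excluded <- detectArtifactFrames(sm, k = 3)
  usable <- setdiff(seq_len(dim(sm@frames)[3]), excluded)
  mip <- matrix(0, dim(sm@frames)[1], dim(sm@frames)[2])
  for (i in 2:length(usable))
    mip <- pmax(mip, abs(sm@frames[, , usable[i]] -
                           sm@frames[, , usable[i - 1L]]))
  fd <- den@destructionFrame
  pre <- den@frames[, , seq_len(fd - 1L), drop = FALSE]
  list(den = den, excluded = excluded, mip = mip,
       ref = apply(pre, c(1, 2), mean))
}

extractFromPrepared <- function(prep, roi, q = quantizationParams(),
                                beamWidth = 1) {
  mip <- prep$mip
  mip[!roi@mask] <- 0
  vessel <- binarizeVessels(mip, roi, sourceScan = prep$den@scanID,
                            excluded = prep$excluded)
  fit <- fitReplenishment(prep$den, roi, excluded = prep$excluded,
                          beamWidth = beamWidth)
  out <- c(firstOrderFeatures(prep$ref, roi, q),
           texturalFeatures(prep$ref, roi, q),
           vascularFeatures(vessel, roi, fit),
           waveletSubbandFeatures(prep$ref, roi, q))
  stopifnot(length(out) == 235L, all(is.finite(out)))
  out
}

#' Build the radiomic feature table of a synthetic study
#'
#' Extracts the 235-feature vector for every (scan, user, dataset)
#' combination of a [CEUSStudy-class]: 28 scans x 3 users x 2 datasets
#' under the default design. Per-sequence intermediates (denoising,
#' smoothing, artifact detection, difference projection) are computed
#' once and shared across the three user delineations.
#'
#' @param study a [CEUSStudy-class] from [generateStudy()].
#' @param q [quantizationParams()].
#' @param denoise a [denoiseParams()] object or `NULL`.
#' @param beamWidth velocity calibration constant.
#' @param verbose print progress.
#' @return a [RadiomicFeatureSet-class] (features x samples) whose
#'   `colData` holds scanID, mouseID, modelLabel, positionID, userID
#'   and datasetID.
#' @export
buildFeatureTable <- function(study, q = quantizationParams(),
                              denoise = denoiseParams(), beamWidth = 1,
                              verbose = FALSE) {
  cols <- list(); meta <- NULL
  for (i in seq_along(study@scans)) {
    scan <- study@scans[[i]]
    for (ds in c("test", "retest")) {
      seq <- scan[[ds]]
      prep <- prepareSequence(seq, denoise)
      for (u in seq_along(scan$rois)) {
        roi <- scan$rois[[u]]
        vec <- extractFromPrepared(prep, roi, q, beamWidth)
        cols[[length(cols) + 1L]] <- vec
        meta <- rbind(meta, data.frame(
          scanID = seq@scanID, mouseID = seq@mouseID,
          modelLabel = seq@modelLabel, positionID = seq@positionID,
          userID = roi@userID, datasetID = seq@datasetID,
          stringsAsFactors = FALSE))
      }
      if (verbose)
        message("extracted ", seq@scanID, " dataset ", seq@datasetID)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- sprintf("%s.u%s.d%s", meta$scanID,
                           sub("user", "", meta$userID), meta$datasetID)
  radiomicFeatureSet(mat, meta)
}

#' Construct a RadiomicFeatureSet
#'
#' @param mat numeric matrix, features in rows, samples in columns.
#' @param meta data.frame of per-sample metadata (one row per column).
#' @return a [RadiomicFeatureSet-class].
#' @export
radiomicFeatureSet <- function(mat, meta) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(featureClass = featureClassOf(rownames(mat))),
    colData = S4Vectors::DataFrame(meta))
  new("RadiomicFeatureSet", se)
}

#' Feature matrix of a sample subset
#'
#' Convenience accessor: the (samples x features) numeric matrix of the
#' columns matching the given user and dataset.
#'
#' @param fs a [RadiomicFeatureSet-class].
#' @param userID,datasetID optional filters.
#' @return matrix with samples in rows (ordered by scanID) and features
#'   in columns.
#' @export
featureMatrix <- function(fs, userID = NULL, datasetID = NULL) {
  cd <- SummarizedExperiment::colData(fs)
  keep <- rep(TRUE, ncol(fs))
  if (!is.null(userID)) keep <- keep & cd$userID == userID
  if (!is.null(datasetID)) keep <- keep & cd$datasetID == datasetID
  sub <- fs[, keep]
  ord <- order(SummarizedExperiment::colData(sub)$scanID)
  t(SummarizedExperiment::assay(sub)[, ord, drop = FALSE])
}
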