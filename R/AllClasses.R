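#' @import methods
#' @importFrom stats median sd var cor mad rnorm runif rexp quantile
#'   pchisq pnorm qnorm dmultinom binom.test kruskal.test quade.test
#'   aov TukeyHSD dist hclust cutree rank setNames predict coef resid
#'   na.omit
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Phantom configuration for synthetic CEUS sequences
#'
#' Parameters of one synthetic destruction--replenishment scan: geometry,
#' acquisition timing, vascular architecture, replenishment kinetics
#' \eqn{A(1 - e^{-\beta t})}, speckle statistics and breathing-motion
#' artifacts. Three phenotype presets (`"P1"`, `"P2"`, `"P3"`) encode
#' tumour models that differ in vascular density, perfusion rate and
#' echogenicity.
#'
#' @slot imageSize integer(2), image height and width in pixels.
#' @slot nFrames integer, number of frames in the sequence.
#' @slot frameRate numeric, frames per second.
#' @slot destructionFrame integer, index of the microbubble destruction
#'   frame (must be < `nFrames`).
#' @slot phenotype character, one of `"P1"`, `"P2"`, `"P3"`.
#' @slot vesselDensity numeric, target vessel-pixel fraction of the ROI.
#' @slot nSeedsVessels integer, number of vessel-tree root points.
#' @slot branchProbability numeric, per-step branching probability of the
#'   random-walk vessel growth.
#' @slot replenishmentRateBeta numeric, replenishment rate \eqn{\beta}
#'   in 1/s.
#' @slot plateauAmplitudeA numeric, microbubble plateau amplitude
#'   \eqn{A} in intensity units.
#' @slot backgroundLevel numeric, mean tissue background intensity.
#' @slot speckleScale numeric, standard deviation of the smoothed
#'   speckle field in intensity units (0 = noiseless).
#' @slot speckleTemporalFrac numeric in [0, 1], fraction of the speckle
#'   variance that fluctuates from frame to frame; the rest is a static
#'   interference texture, as for tissue with a fixed scatterer
#'   configuration.
#' @slot textureGranularity numeric, speckle correlation length (pixels).
#' @slot breathingPeriod integer, a breathing-shifted frame is inserted
#'   every this many frames (0 disables motion artifacts).
#' @slot breathingShift integer, artifact displacement in pixels.
#' @slot rngSeed integer, seed controlling the phantom geometry.
#' @export
setClass("PhantomConfig", representation(
  imageSize = "integer", nFrames = "integer", frameRate = "numeric",
  destructionFrame = "integer", phenotype = "character",
  vesselDensity = "numeric", nSeedsVessels = "integer",
  branchProbability = "numeric", replenishmentRateBeta = "numeric",
  plateauAmplitudeA = "numeric", backgroundLevel = "numeric",
  speckleScale = "numeric", speckleTemporalFrac = "numeric",
  textureGranularity = "numeric",
  breathingPeriod = "integer", breathingShift = "integer",
  rngSeed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be two integers >= 16")
  if (object@vesselDensity < 0 || object@vesselDensity >= 1)
    msg <- c(msg, "vesselDensity must lie in [0, 1)")
  if (object@destructionFrame >= object@nFrames)
    msg <- c(msg, "destructionFrame must be < nFrames")
  if (object@destructionFrame < 2L)
    msg <- c(msg, "destructionFrame must be >= 2")
  if (object@replenishmentRateBeta <= 0)
    msg <- c(msg, "replenishmentRateBeta must be > 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (!object@phenotype %in% c("P1", "P2", "P3"))
    msg <- c(msg, "phenotype must be one of P1, P2, P3")
  if (length(msg)) msg else TRUE
})

#' Time-resolved CEUS intensity sequence
#'
#' A linear-scale B-mode intensity stack (height x width x time) with the
#' acquisition metadata needed by the destruction--replenishment analysis.
#'
#' @slot frames numeric 3-D array (y, x, t), non-negative linear
#'   intensities.
#' @slot frameRate numeric, frames per second.
#' @slot destructionFrame integer, index of the destruction frame.
#' @slot scanID,mouseID,modelLabel,positionID,datasetID character
#'   identifiers.
#' @export
setClass("CEUSSequence", representation(
  frames = "array", frameRate = "numeric", destructionFrame = "integer",
  scanID = "character", mouseID = "character", modelLabel = "character",
  positionID = "character", datasetID = "character"))

setValidity("CEUSSequence", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (y, x, t)")
  if (any(!is.finite(object@frames)) || any(object@frames < 0))
    msg <- c(msg, "frame intensities must be finite and >= 0")
  if (object@destructionFrame >= dim(object@frames)[3])
    msg <- c(msg, "destructionFrame must be < number of frames")
  if (length(msg)) msg else TRUE
})

#' Binary tumour region-of-interest mask
#'
#' @slot mask logical matrix on the image grid; non-empty with a single
#'   connected (8-neighbourhood) foreground component.
#' @slot userID character, identifier of the delineating user.
#' @export
setClass("ROIMask", representation(mask = "matrix", userID = "character"))

setValidity("ROIMask", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be a logical matrix")
  if (!any(m)) return("ROI mask must be non-empty")
  if (max(label8(m)) != 1L)
    return("ROI mask must have a single connected component")
  TRUE
})

#' Binary vessel segmentation mask
#'
#' @slot mask logical matrix, vessel pixels inside the ROI.
#' @slot excludedFrames integer, frames dropped as breathing artifacts.
#' @slot sourceScan character, scan the mask was derived from.
#' @export
setClass("VesselMask", representation(
  mask = "matrix", excludedFrames = "integer", sourceScan = "character"))

#' Fitted replenishment kinetics
#'
#' Parameters of the post-destruction time--intensity model
#' \eqn{I(t) = I_0 + A(1 - e^{-\beta t})}.
#'
#' @slot I0 numeric, intensity at the destruction time point.
#' @slot A numeric, plateau amplitude (>= 0).
#' @slot beta numeric, replenishment rate in 1/s (>= 0).
#' @slot velocity numeric, mean blood flow velocity `beta * beamWidth`.
#' @slot rmse numeric, root-mean-square residual of the fit.
#' @export
setClass("ReplenishmentFit", representation(
  I0 = "numeric", A = "numeric", beta = "numeric", velocity = "numeric",
  rmse = "numeric"))

#' Ground truth of a synthetic phantom
#'
#' @slot trueROI logical matrix, the true tumour delineation.
#' @slot trueVesselMask logical matrix, the rendered vessel network.
#' @slot trueBeta numeric, configured replenishment rate (1/s).
#' @slot trueRBV numeric, vessel-pixel fraction of the ROI.
#' @slot trueNetworkLength numeric, skeleton length of the vessel tree
#'   in pixels.
#' @slot trueArtifactFrames integer, indices of breathing-shifted frames.
#' @export
setClass("GroundTruth", representation(
  trueROI = "matrix", trueVesselMask = "matrix", trueBeta = "numeric",
  trueRBV = "numeric", trueNetworkLength = "numeric",
  trueArtifactFrames = "integer"))

#' A synthetic CEUS study bundle
#'
#' Test and retest acquisitions of each tumour position, shared ground
#' truth, and three per-user ROI delineations, mirroring a two-dataset
#' test/retest design (14 animals, two positions each, 28 scans per
#' dataset by default).
#'
#' @slot scans list; each element holds `test` and `retest`
#'   [CEUSSequence-class] renders, a [GroundTruth-class], and a list of
#'   three [ROIMask-class] objects.
#' @slot manifest data.frame with one row per scan (scanID, mouseID,
#'   modelLabel, positionID).
#' @export
setClass("CEUSStudy", representation(scans = "list", manifest = "data.frame"))

#' Radiomic feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with the 235 radiomic
#' features as rows and one column per (scan, user, dataset)
#' combination. `rowData()$featureClass` assigns each feature to one of
#' the four imaging biomarker classes (`first_order`, `textural`,
#' `vascular`, `wavelet`); `colData()` carries the scan metadata.
#'
#' @export
setClass("RadiomicFeatureSet", contains = "SummarizedExperiment")

setValidity("RadiomicFeatureSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"featureClass" %in% colnames(rd))
    return("rowData must contain a featureClass column")
  if (any(!rd$featureClass %in%
          c("first_order", "textural", "vascular", "wavelet")))
    return("unknown featureClass")
  TRUE
})

#' Selected radiomic signature
#'
#' Four feature names, one per imaging biomarker class, with the Pearson
#' correlation matrix of their values (all pairwise |r| below the
#' pruning threshold).
#'
#' @slot features character(4), selected feature names.
#' @slot classes character(4), biomarker class of each feature.
#' @slot corMatrix numeric 4x4 Pearson correlation matrix.
#' @export
setClass("RadiomicSignature", representation(
  features = "character", classes = "character", corMatrix = "matrix"))

#' Cross-validated classification result
#'
#' @slot confusion integer matrix of counts, true classes in rows,
#'   predicted classes in columns, pooled over held-out folds.
#' @slot accuracy numeric, pooled fraction of correct predictions.
#' @slot wilsonCI numeric(2), 95\% Wilson score interval of the accuracy.
#' @slot folds integer, fold assignment per sample.
#' @export
setClass("ClassificationResult", representation(
  confusion = "matrix", accuracy = "numeric", wilsonCI = "numeric",
  folds = "integer"))

#' Hierarchical clustering result
#'
#' @slot tree the `hclust` linkage tree (Euclidean distance, average
#'   linkage).
#' @slot labels integer cluster label per sample after cutting the tree.
#' @slot enrichment data.frame of per-(cluster, model) exact tests, or
#'   an empty data.frame if not yet computed.
#' @export
setClass("ClusterResult", representation(
  tree = "ANY", labels = "integer", enrichment = "data.frame"))

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig [", object@phenotype, "] ",
      object@imageSize[1], "x", object@imageSize[2], " px, ",
      object@nFrames, " frames @ ", object@frameRate, " fps\n",
      "  vesselDensity=", object@vesselDensity,
      "  beta=", object@replenishmentRateBeta, "/s",
      "  A=", object@plateauAmplitudeA,
      "  speckleScale=", object@speckleScale,
      "  seed=", object@rngSeed, "\n", sep = "")
})

setMethod("show", "CEUSSequence", function(object) {
  d <- dim(object@frames)
  cat("CEUSSequence ", object@scanID, " [", object@modelLabel, "] ",
      d[1], "x", d[2], " px, ", d[3], " frames @ ", object@frameRate,
      " fps, destruction at frame ", object@destructionFrame,
      " (dataset ", object@datasetID, ")\n", sep = "")
})

setMethod("show", "CEUSStudy", function(object) {
  cat("CEUSStudy:", length(object@scans), "tumour positions,",
      2L * length(object@scans), "scans (test + retest)\n")
  print(table(object@manifest$modelLabel))
})

setMethod("show", "RadiomicSignature", function(object) {
  cat("RadiomicSignature (one feature per biomarker class):\n")
  for (i in seq_along(object@features))
    cat(sprintf("  %-12s %s\n", object@classes[i], object@features[i]))
  cat("max off-diagonal |r| =",
      round(max(abs(object@corMatrix[upper.tri(object@corMatrix)])), 3), "\n")
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: accuracy %.1f%% (95%% CI [%.2f %.2f])\n",
              100 * object@accuracy, object@wilsonCI[1], object@wilsonCI[2]))
  print(object@confusion)
})
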