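#' Accessors for CEUS data objects
#'
#' Small accessor generics for the package's S4 containers, in place of
#' direct slot access.
#'
#' @param object an object of the matching class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityFrames", function(object)
  standardGeneric("intensityFrames"))
#' @rdname accessors
#' @export
setMethod("intensityFrames", "CEUSSequence", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "CEUSSequence", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("destructionFrame", function(object)
  standardGeneric("destructionFrame"))
#' @rdname accessors
#' @export
setMethod("destructionFrame", "CEUSSequence", function(object)
  object@destructionFrame)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "CEUSSequence", function(object)
  dim(object@frames)[3])

#' @rdname accessors
#' @export
setGeneric("scanID", function(object) standardGeneric("scanID"))
#' @rdname accessors
#' @export
setMethod("scanID", "CEUSSequence", function(object) object@scanID)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ROIMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "VesselMask", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("excludedFrames", function(object)
  standardGeneric("excludedFrames"))
#' @rdname accessors
#' @export
setMethod("excludedFrames", "VesselMask", function(object)
  object@excludedFrames)

#' @rdname accessors
#' @export
setGeneric("featureClasses", function(object)
  standardGeneric("featureClasses"))
#' @rdname accessors
#' @export
setMethod("featureClasses", "RadiomicFeatureSet", function(object)
  setNames(SummarizedExperiment::rowData(object)$featureClass,
           rownames(object)))

#' @rdname accessors
#' @export
setGeneric("signatureFeatures", function(object)
  standardGeneric("signatureFeatures"))
#' @rdname accessors
#' @export
setMethod("signatureFeatures", "RadiomicSignature", function(object)
  object@features)

#' @rdname accessors
#' @export
setGeneric("signatureClasses", function(object)
  standardGeneric("signatureClasses"))
#' @rdname accessors
#' @export
setMethod("signatureClasses", "RadiomicSignature", function(object)
  object@classes)

#' @rdname accessors
#' @export
setGeneric("signatureCor", function(object) standardGeneric("signatureCor"))
#' @rdname accessors
#' @export
setMethod("signatureCor", "RadiomicSignature", function(object)
  object@corMatrix)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setMethod("accuracy", "ClassificationResult", function(object)
  object@accuracy)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object)
  standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "ClassificationResult", function(object)
  object@confusion)

#' @rdname accessors
#' @export
setGeneric("wilsonCI", function(object) standardGeneric("wilsonCI"))
#' @rdname accessors
#' @export
setMethod("wilsonCI", "ClassificationResult", function(object)
  object@wilsonCI)

#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(object)
  standardGeneric("foldAssignments"))
#' @rdname accessors
#' @export
setMethod("foldAssignments", "ClassificationResult", function(object)
  object@folds)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object)
  standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object, ...) standardGeneric("groundTruth"))
#' @rdname accessors
#' @param i scan index within the study.
#' @param ... unused.
#' @export
setMethod("groundTruth", "CEUSStudy", function(object, i = 1L, ...)
  object@scans[[i]]$truth)

#' @rdname accessors
#' @export
setGeneric("studyManifest", function(object) standardGeneric("studyManifest"))
#' @rdname accessors
#' @export
setMethod("studyManifest", "CEUSStudy", function(object) object@manifest)
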