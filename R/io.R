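# On-disk interchange: multi-page 32-bit float TIFF per sequence (one
# page per frame), single-page TIFF masks, and a JSON sidecar with the
# acquisition metadata. Intensities are stored divided by a scale
# factor recorded in the sidecar, since TIFF float pages are written in
# [0, 1].

#' Write / read a CEUS sequence as TIFF + JSON sidecar
#'
#' @param seq a [CEUSSequence-class].
#' @param path output TIFF path; the sidecar is written next to it with
#'   a `.json` extension.
#' @return `writeCEUSSequence` returns `path` invisibly;
#'   `readCEUSSequence` returns the reconstructed
#'   [CEUSSequence-class].
#' @export
writeCEUSSequence <- function(seq, path) {
  fr <- seq@frames
  scale <- max(fr, 1e-12)
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = scale, frameRate = seq@frameRate,
               destructionFrame = seq@destructionFrame,
               scanID = seq@scanID, mouseID = seq@mouseID,
               modelLabel = seq@modelLabel, positionID = seq@positionID,
               datasetID = seq@datasetID)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCEUSSequence
#' @export
readCEUSSequence <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  fr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]] * meta$scale
  new("CEUSSequence", frames = fr, frameRate = meta$frameRate,
      destructionFrame = as.integer(meta$destructionFrame),
      scanID = meta$scanID, mouseID = meta$mouseID,
      modelLabel = meta$modelLabel, positionID = meta$positionID,
      datasetID = meta$datasetID)
}

sidecarPath <- function(path) sub("\\.[^.]*$", ".json", path)

#' Write / read a binary mask as single-page TIFF
#'
#' @param mask logical matrix, an [ROIMask-class] or a
#'   [VesselMask-class].
#' @param path output TIFF path.
#' @export
writeMaskTIFF <- function(mask, path) {
  m <- if (is.matrix(mask)) mask else maskMatrix(mask)
  tiff::writeTIFF((m != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMaskTIFF
#' @export
readMaskTIFF <- function(path) {
  as.matrix(tiff::readTIFF(path)) > 0.5
}

#' Export a study to a directory
#'
#' Writes every sequence (both datasets) as multi-page TIFF with JSON
#' sidecars, the three user ROI masks per scan, and a `manifest.csv`
#' indexing the files.
#'
#' @param study a [CEUSStudy-class].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(study@scans)) {
    scan <- study@scans[[i]]
    for (ds in c("test", "retest")) {
      seq <- scan[[ds]]
      base <- sprintf("%s_d%s", seq@scanID, seq@datasetID)
      writeCEUSSequence(seq, file.path(dir, paste0(base, ".tif")))
      rows[[length(rows) + 1L]] <- data.frame(
        scanID = seq@scanID, mouseID = seq@mouseID,
        modelLabel = seq@modelLabel, positionID = seq@positionID,
        dataset = seq@datasetID, file = paste0(base, ".tif"),
        stringsAsFactors = FALSE)
    }
    for (u in seq_along(scan$rois))
      writeMaskTIFF(scan$rois[[u]],
                    file.path(dir, sprintf("%s_roi_user%d.tif",
                                           scan$test@scanID, u)))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write a feature table to CSV
#'
#' One row per (scan, user, dataset) with the metadata columns followed
#' by the 235 feature columns.
#'
#' @param fs a [RadiomicFeatureSet-class].
#' @param path output CSV path.
#' @export
writeFeatureCSV <- function(fs, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  mat <- t(SummarizedExperiment::assay(fs))
  utils::write.csv(cbind(cd, as.data.frame(mat)), path, row.names = FALSE)
  invisible(path)
}
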