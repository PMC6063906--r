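#' Denoising parameters
#'
#' Settings of the log-domain wavelet speckle filter. Multiplicative
#' speckle becomes approximately additive after a log transform; the
#' image is decomposed with a biorthogonal 3.7 wavelet to `level`
#' levels, the BayesShrink threshold is computed for each detail subband
#' of the deepest level, and those coefficients are soft-thresholded
#' before reconstruction.
#'
#' @param wavelet wavelet name (default `"bior3.7"`).
#' @param level decomposition depth (default 3).
#' @param logOffset positive offset added before the log transform to
#'   guard `log(0)` (default 1 intensity unit).
#' @param thresholdScale multiplier applied to the BayesShrink
#'   thresholds; 0 disables shrinkage entirely (useful to verify the
#'   perfect-reconstruction path), 1 is the standard rule.
#' @return a `DenoiseParams` list.
#' @export
denoiseParams <- function(wavelet = "bior3.7", level = 3L, logOffset = 1,
                          thresholdScale = 1) {
  stopifnot(level >= 1L, logOffset > 0, thresholdScale >= 0)
  waveletFilters(wavelet)  # validates the name
  structure(list(wavelet = wavelet, level = as.integer(level),
                 logOffset = logOffset, thresholdScale = thresholdScale),
            class = "DenoiseParams")
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# BayesShrink threshold for one subband: T = sigma_n^2 / sigma_x with
# sigma_x^2 = max(var(subband) - sigma_n^2, 0); when the subband is all
# noise (sigma_x = 0) every coefficient is removed.
bayesThreshold <- function(coefs, sigmaN) {
  sigmaY2 <- mean(coefs^2)
  sigmaX <- sqrt(max(sigmaY2 - sigmaN^2, 0))
  if (sigmaX == 0) max(abs(coefs)) else sigmaN^2 / sigmaX
}

#' Wavelet speckle denoising of a B-mode frame
#'
#' Log-transforms the image, performs a level-`level` 2-D wavelet
#' decomposition, estimates the noise level as
#' `median(|HH1|) / 0.6745` from the first-level diagonal detail,
#' soft-thresholds the detail subbands of the deepest level with the
#' BayesShrink threshold, reconstructs, and inverts the log transform.
#' Only the deepest-level details are shrunk; shallower levels and the
#' approximation pass through unchanged.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param params a [denoiseParams()] object.
#' @return denoised matrix, same shape, clipped at 0.
#' @export
denoiseFrame <- function(image, params = denoiseParams()) {
  stopifnot(is.matrix(image), all(is.finite(image)), all(image >= 0))
  if (min(dim(image)) < 2L^params$level)
    stop("image too small for a level-", params$level, " decomposition")
  lx <- log(image + params$logOffset)
  dec <- dwt2(lx, wavelet = params$wavelet, level = params$level)
  sigmaN <- median(abs(dec$details[[1]]$HH)) / 0.6745
  deep <- dec$details[[params$level]]
  for (nm in c("LH", "HL", "HH")) {
    th <- params$thresholdScale * bayesThreshold(deep[[nm]], sigmaN)
    deep[[nm]] <- softThreshold(deep[[nm]], th)
  }
  dec$details[[params$level]] <- deep
  out <- exp(idwt2(dec)) - params$logOffset
  pmax(out, 0)
}

#' Framewise denoising of a CEUS sequence
#'
#' Applies [denoiseFrame()] to every frame; all acquisition metadata is
#' preserved.
#'
#' @param seq a [CEUSSequence-class].
#' @param params a [denoiseParams()] object.
#' @return a denoised [CEUSSequence-class].
#' @export
denoiseSequence <- function(seq, params = denoiseParams()) {
  fr <- seq@frames
  for (t in seq_len(dim(fr)[3]))
    fr[, , t] <- denoiseFrame(fr[, , t], params)
  new("CEUSSequence", frames = fr, frameRate = seq@frameRate,
      destructionFrame = seq@destructionFrame, scanID = seq@scanID,
      mouseID = seq@mouseID, modelLabel = seq@modelLabel,
      positionID = seq@positionID, datasetID = seq@datasetID)
}
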