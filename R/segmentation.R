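#' Local adaptive (Wiener-type) smoothing
#'
#' Pixel-wise linear minimum-mean-square-error filter over a square
#' window: `out = m + max(v - vn, 0) / max(v, eps) * (x - m)` with local
#' mean `m`, local variance `v`, and noise variance `vn` estimated as
#' the mean of the local variances. Flat regions are replaced by the
#' local mean; structured regions pass through.
#'
#' @param frame numeric matrix.
#' @param kernel odd window size (default 3).
#' @param eps variance floor.
#' @return smoothed matrix, same shape.
#' @export
adaptiveSmooth <- function(frame, kernel = 3L, eps = 1e-12) {
  stopifnot(all(is.finite(frame)), kernel %% 2L == 1L)
  m <- localMean(frame, kernel)
  v <- pmax(localMean(frame^2, kernel) - m^2, 0)
  vn <- mean(v)
  m + pmax(v - vn, 0) / pmax(v, eps) * (frame - m)
}

#' Detect breathing-artifact frames
#'
#' Scores every frame by the mean absolute difference to its
#' predecessor and flags outliers above `median + k * MAD`. A breathing
#' displacement is transient and reversible: an artifact frame shows a
#' high score on both its entering and leaving transition while its two
#' neighbours remain mutually similar -- the skip difference
#' |frame(t+1) - frame(t-1)| stays well below both transitions.
#' Persistent intensity changes -- the bolus inflow ramp and the
#' destruction event -- fail the reversibility condition and are not
#' flagged.
#'
#' @param seq a [CEUSSequence-class] (>= 3 frames).
#' @param k MAD multiplier (default 3).
#' @return integer vector of artifact frame indices (possibly empty).
#' @export
detectArtifactFrames <- function(seq, k = 3) {
  fr <- seq@frames
  nT <- dim(fr)[3]
  stopifnot(nT >= 3L)
  frameDiff <- function(a, b) mean(abs(fr[, , a] - fr[, , b]))
  s <- c(NA, vapply(2:nT, function(t) frameDiff(t, t - 1L), numeric(1)))
  thr <- median(s[-1]) + k * mad(s[-1])
  flagged <- which(vapply(seq_len(nT), function(t) {
    if (t == 1L || s[t] <= thr) return(FALSE)
    if (t == nT) return(TRUE)               # cannot verify reversibility
    if (s[t + 1L] <= thr) return(FALSE)
    skip <- frameDiff(t + 1L, t - 1L)
    skip < 0.5 * min(s[t], s[t + 1L])
  }, logical(1)))
  as.integer(flagged)
}

#' Maximum intensity projection of frame differences
#'
#' Computes |frame(t) - frame(t-1)| over consecutive usable (non-
#' excluded) frame pairs and takes the per-pixel maximum over time,
#' masked to the ROI. Moving microbubbles change between frames and
#' accumulate into bright curvilinear traces; static tissue echoes
#' cancel.
#'
#' @param seq a [CEUSSequence-class].
#' @param roi an [ROIMask-class].
#' @param excluded integer frame indices to drop (breathing artifacts).
#' @return numeric matrix (0 outside the ROI).
#' @export
motionMIP <- function(seq, roi, excluded = integer(0)) {
  fr <- seq@frames
  usable <- setdiff(seq_len(dim(fr)[3]), excluded)
  if (length(usable) < 2L)
    stop("need at least 2 usable frames for the difference projection")
  mip <- matrix(0, dim(fr)[1], dim(fr)[2])
  for (i in 2:length(usable)) {
    d <- abs(fr[, , usable[i]] - fr[, , usable[i - 1L]])
    mip <- pmax(mip, d)
  }
  mip[!roi@mask] <- 0
  mip
}

#' Binarize the motion projection into a vessel mask
#'
#' Local-mean adaptive thresholding of the projection (window `window`,
#' additive offset `offset`), restricted to the ROI, followed by
#' removal of 8-connected components smaller than `minSize` pixels
#' (speckle remnants). Pixels outside the ROI are filled with the ROI
#' median before the local mean is computed so the ROI boundary does not
#' bias the threshold.
#'
#' @param mip numeric matrix from [motionMIP()].
#' @param roi an [ROIMask-class].
#' @param window local-mean window in pixels (odd; default 15).
#' @param offset additive threshold offset; the default `NULL` uses
#'   half the standard deviation of the projection inside the ROI,
#'   which adapts the margin to the residual speckle level.
#' @param minSize minimum surviving component size (default 5 px).
#' @param sourceScan identifier stored in the result.
#' @param excluded artifact frames recorded in the result.
#' @return a [VesselMask-class].
#' @export
binarizeVessels <- function(mip, roi, window = 15L, offset = NULL,
                            minSize = 5L, sourceScan = "scan",
                            excluded = integer(0)) {
  if (!any(roi@mask)) stop("empty ROI")
  vals <- mip[roi@mask]
  if (is.null(offset)) offset <- 0.5 * sd(vals)
  if (!is.finite(offset)) offset <- 0
  filled <- mip
  filled[!roi@mask] <- median(vals)
  bg <- localMean(filled, as.integer(window))
  bin <- (mip > bg + offset) & roi@mask
  if (any(bin)) {
    lab <- label8(bin)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minSize)
    bin <- matrix(lab %in% keep & lab > 0L, nrow(bin), ncol(bin))
  }
  new("VesselMask", mask = bin, excludedFrames = as.integer(excluded),
      sourceScan = sourceScan)
}

#' Fit post-destruction replenishment kinetics
#'
#' Builds the ROI-mean time--intensity curve of the non-excluded frames
#' from the destruction frame onward (time in seconds from destruction)
#' and fits \eqn{I(t) = I_0 + A (1 - e^{-\beta t})} by nonlinear least
#' squares. The mean blood flow velocity is `beta * beamWidth`, with
#' `beamWidth` the elevational beam-geometry calibration constant.
#'
#' @param seq a [CEUSSequence-class] with a destruction frame and at
#'   least 5 usable post-destruction frames.
#' @param roi an [ROIMask-class].
#' @param excluded artifact frame indices to drop.
#' @param beamWidth calibration constant (length units; default 1).
#' @return a [ReplenishmentFit-class].
#' @export
fitReplenishment <- function(seq, roi, excluded = integer(0),
                             beamWidth = 1) {
  fd <- seq@destructionFrame
  nT <- dim(seq@frames)[3]
  frames <- setdiff(fd:nT, excluded)
  if (length(frames) < 5L)
    stop("need at least 5 usable post-destruction frames")
  tt <- (frames - fd) / seq@frameRate
  I <- vapply(frames, function(f) mean(seq@frames[, , f][roi@mask]),
              numeric(1))
  if (sd(I) < 1e-10) {                      # flat curve: degenerate fit
    return(new("ReplenishmentFit", I0 = mean(I), A = 0, beta = 0,
               velocity = 0, rmse = sd(I)))
  }
  start <- list(I0 = I[1], A = max(I[length(I)] - I[1], 1e-6),
                beta = 2 / max(tt))
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 + A * (1 - exp(-beta * tt)),
                      start = start,
                      lower = c(I0 = 0, A = 0, beta = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("replenishment fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  new("ReplenishmentFit", I0 = unname(cf["I0"]), A = unname(cf["A"]),
      beta = unname(cf["beta"]),
      velocity = unname(cf["beta"]) * beamWidth,
      rmse = sqrt(mean(resid(fit)^2)))
}

#' Segment the perfused vasculature of a CEUS scan
#'
#' Runs the full segmentation chain: 3x3 adaptive (Wiener-type)
#' smoothing of every frame, breathing-artifact detection and
#' exclusion, maximum intensity projection of the frame differences,
#' adaptive thresholding, and small-speckle removal.
#'
#' @param seq a [CEUSSequence-class] (typically already denoised).
#' @param roi an [ROIMask-class].
#' @param window,offset,minSize passed to [binarizeVessels()].
#' @param madK MAD multiplier for [detectArtifactFrames()].
#' @return a [VesselMask-class] with the excluded frames recorded.
#' @export
segmentVessels <- function(seq, roi, window = 15L, offset = NULL,
                           minSize = 5L, madK = 3) {
  smoothed <- seq
  for (t in seq_len(dim(seq@frames)[3]))
    smoothed@frames[, , t] <- adaptiveSmooth(seq@frames[, , t])
  excluded <- detectArtifactFrames(smoothed, k = madK)
  mip <- motionMIP(smoothed, roi, excluded)
  binarizeVessels(mip, roi, window = window, offset = offset,
                  minSize = minSize, sourceScan = seq@scanID,
                  excluded = excluded)
}
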