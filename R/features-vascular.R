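# erode the ROI until its area first drops to <= 50% of the original;
# returns the core mask (possibly empty for degenerate ROIs)
roiCore <- function(roiMask) {
  brush <- EBImage::makeBrush(3L, shape = "box")
  core <- roiMask
  target <- sum(roiMask) / 2
  while (sum(core) > target) {
    eroded <- as.matrix(EBImage::imageData(
      EBImage::erode(core * 1, brush))) > 0
    if (sum(eroded) == sum(core)) break   # erosion stalled
    core <- eroded
  }
  core
}

#' Vascular morphometry and perfusion features (15 features)
#'
#' Morphological and functional characterization of the segmented
#' tumour vasculature: component counts and sizes, skeleton network
#' length and branch points, the Euclidean distance map from non-vessel
#' ROI pixels to the nearest vessel, relative blood volume (rBV) with
#' its periphery/core decomposition (core = innermost 50\% of the ROI
#' area by iterative erosion), and the mean blood flow velocity from
#' the replenishment fit.
#'
#' With an empty vessel mask the counts are 0 and all distance features
#' take the ROI's internal maximum feasible distance (distance to the
#' ROI boundary). A core rBV of 0 makes the periphery/core ratio
#' undefined; it is reported as the sentinel 0.
#'
#' @param vessel a [VesselMask-class] or logical matrix.
#' @param roi an [ROIMask-class] or logical matrix.
#' @param fit a [ReplenishmentFit-class] supplying the velocity.
#' @return named numeric vector of 15 features.
#' @export
vascularFeatures <- function(vessel, roi, fit) {
  v <- if (is(vessel, "VesselMask")) vessel@mask else vessel
  r <- if (is(roi, "ROIMask")) roi@mask else roi
  stopifnot(all(dim(v) == dim(r)))
  v <- v & r
  nROI <- sum(r)
  sizes <- componentSizes(v)
  nVessels <- length(sizes)
  skel <- if (any(v)) skeletonize(v) else v
  networkLength <- sum(skel)
  if (any(v)) {
    dm <- as.matrix(EBImage::imageData(EBImage::distmap(!v * 1)))
    dvals <- dm[r & !v]
    if (length(dvals) == 0L) dvals <- 0     # vessel mask fills the ROI
    distMean <- mean(dvals); distSD <- if (length(dvals) > 1L) sd(dvals) else 0
    distMax <- max(dvals)
  } else {
    inner <- as.matrix(EBImage::imageData(EBImage::distmap(r * 1)))
    distMean <- distMax <- max(inner)
    distSD <- 0
  }
  core <- roiCore(r)
  periphery <- r & !core
  rbv <- sum(v) / nROI
  rbvCore <- if (sum(core) > 0) sum(v & core) / sum(core) else 0
  rbvPeriph <- if (sum(periphery) > 0) sum(v & periphery) / sum(periphery) else 0
  ratio <- if (rbvCore > 0) rbvPeriph / rbvCore else 0
  c(vascular_n_vessels = nVessels,
    vascular_mean_vessel_size = if (nVessels) mean(sizes) else 0,
    vascular_median_vessel_size = if (nVessels) median(sizes) else 0,
    vascular_network_length = networkLength,
    vascular_dist_mean = distMean,
    vascular_dist_sd = distSD,
    vascular_dist_max = distMax,
    vascular_rbv = rbv,
    vascular_rbv_periphery_core = ratio,
    vascular_velocity = fit@velocity,
    vascular_total_area = sum(v),
    vascular_max_vessel_size = if (nVessels) max(sizes) else 0,
    vascular_n_branch_points = if (any(v)) branchPoints(skel) else 0,
    vascular_rbv_periphery = rbvPeriph,
    vascular_rbv_core = rbvCore)
}

#' Wavelet-subband features (176 features)
#'
#' Level-1 stationary (undecimated) wavelet transform with the
#' coiflet-1 wavelet yields four same-size subbands (approximation A
#' and the H/V/D details); on each subband, restricted to the ROI, the
#' 14 first-order and 30 textural features are computed, giving
#' 4 x 44 = 176 features. Names are prefixed with the subband, e.g.
#' `waveletD_glrlm_RLN` is the run length nonuniformity of the run
#' length matrix on the diagonal details.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 176 features.
#' @export
waveletSubbandFeatures <- function(image, roi, q = quantizationParams()) {
  sub <- swt2(image, wavelet = "coif1")
  out <- numeric(0)
  for (nm in c("A", "H", "V", "D")) {
    f <- c(firstOrderFeatures(sub[[nm]], roi, q),
           texturalFeatures(sub[[nm]], roi, q))
    names(f) <- paste0("wavelet", nm, "_", names(f))
    out <- c(out, f)
  }
  out
}
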