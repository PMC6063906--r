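#' Grey-level quantization parameters
#'
#' Texture matrices need discrete grey levels; intensities are binned
#' into `nLevels` equal-width bins spanning the min--max range of the
#' ROI pixels (each image or wavelet subband is quantized on its own
#' range).
#'
#' @param nLevels number of grey levels (default 32).
#' @export
quantizationParams <- function(nLevels = 32L) {
  stopifnot(nLevels >= 2L)
  structure(list(nLevels = as.integer(nLevels)), class = "QuantizationParams")
}

# quantize image to 1..nLevels inside the ROI, NA elsewhere
quantizeROI <- function(image, roiMask, q = quantizationParams()) {
  vals <- image[roiMask]
  lo <- min(vals); hi <- max(vals)
  out <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    out[roiMask] <- 1L
  } else {
    lev <- pmin(floor((image[roiMask] - lo) / (hi - lo) * q$nLevels) + 1L,
                q$nLevels)
    out[roiMask] <- as.integer(lev)
  }
  out
}

#' First-order intensity statistics (14 features)
#'
#' The standard radiomics first-order set over the ROI pixels: energy
#' (sum of squares), histogram entropy and uniformity (on the quantized
#' histogram), central moments (variance, skewness, kurtosis with
#' population normalization), order statistics, mean absolute
#' deviation, and root-mean-square.
#'
#' @param image numeric matrix.
#' @param roi an [ROIMask-class] or logical matrix.
#' @param q [quantizationParams()] for the histogram-based features.
#' @return named numeric vector of 14 features.
#' @export
firstOrderFeatures <- function(image, roi, q = quantizationParams()) {
  roiMask <- if (is(roi, "ROIMask")) roi@mask else roi
  x <- image[roiMask]
  if (length(x) < 2L) stop("ROI must contain at least 2 pixels")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  qi <- quantizeROI(image, roiMask, q)
  p <- tabulate(qi[roiMask], nbins = q$nLevels) / n
  pz <- p[p > 0]
  c(firstorder_energy = sum(x^2),
    firstorder_entropy = -sum(pz * log2(pz)),
    firstorder_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_maximum = max(x),
    firstorder_mean = mu,
    firstorder_mad = mean(abs(x - mu)),
    firstorder_median = median(x),
    firstorder_minimum = min(x),
    firstorder_range = max(x) - min(x),
    firstorder_rms = sqrt(mean(x^2)),
    firstorder_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_sd = sqrt(m2),
    firstorder_uniformity = sum(p^2),
    firstorder_variance = m2)
}

# the four 2-D directions at distance 1: 0, 45, 90, 135 degrees,
# expressed as (row, col) offsets on the image grid
.glcmOffsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# symmetric normalized co-occurrence matrix for one direction
glcmMatrix <- function(qimg, offset, nLevels) {
  nr <- nrow(qimg); nc <- ncol(qimg)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- qimg[r1, c1, drop = FALSE]
  b <- qimg[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  counts <- matrix(0, nLevels, nLevels)
  if (any(keep)) {
    idx <- (a[keep] - 1L) * nLevels + b[keep]
    tab <- tabulate(idx, nbins = nLevels^2)
    counts <- matrix(tab, nLevels, nLevels, byrow = TRUE)
  }
  counts <- counts + t(counts)            # symmetric pairs
  s <- sum(counts)
  if (s > 0) counts / s else counts
}

glcmStats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)                        # symmetric: px == py
  mux <- sum(seq_len(L) * px)
  sigx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  # diagonal and cross-diagonal marginals
  pxy_diff <- vapply(0:(L - 1L), function(k) sum(P[abs(i - j) == k]),
                     numeric(1))
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[(i + j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(P)
  pipj <- outer(px, px)
  nz <- P > 0 & pipj > 0
  HXY1 <- -sum(P[nz] * log2(pipj[nz]))
  HXY2 <- ent(pipj)
  HX <- ent(px)
  sa <- sum((2:(2 * L)) * pxy_sum)
  corr <- if (sigx > 0) (sum(i * j * P) - mux^2) / sigx^2 else 1
  offd <- i != j
  c(glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_prominence = sum((i + j - 2 * mux)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mux)^3 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_difference_entropy = ent(pxy_diff),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_energy = sum(P^2),
    glcm_entropy = HXY,
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    glcm_imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / L^2)),
    glcm_max_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = ent(pxy_sum),
    glcm_sum_variance = sum(((2:(2 * L)) - sa)^2 * pxy_sum),
    glcm_variance = sum((i - mux)^2 * P),
    glcm_inverse_variance = sum(P[offd] / (i[offd] - j[offd])^2))
}

#' Grey-level co-occurrence features (19 features)
#'
#' Quantizes the ROI, builds symmetric normalized co-occurrence
#' matrices at distance 1 for the requested directions (pairs with both
#' pixels inside the ROI), averages the matrices over directions and
#' returns 19 Haralick-type features.
#'
#' @param image numeric matrix.
#' @param roi an [ROIMask-class] or logical matrix.
#' @param q [quantizationParams()].
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return named numeric vector of 19 features.
#' @export
glcmFeatures <- function(image, roi, q = quantizationParams(),
                         directions = c("0", "45", "90", "135")) {
  roiMask <- if (is(roi, "ROIMask")) roi@mask else roi
  if (sum(roiMask) < 2L) stop("ROI must contain at least 2 pixels")
  qimg <- quantizeROI(image, roiMask, q)
  mats <- lapply(.glcmOffsets[directions], glcmMatrix, qimg = qimg,
                 nLevels = q$nLevels)
  P <- Reduce(`+`, mats) / length(mats)
  glcmStats(P)
}

# maximal constant runs along the scan lines of one direction;
# returns a (level x run length) count matrix
glrlmMatrix <- function(qimg, direction, nLevels) {
  lines <- switch(direction,
    `0` = split(qimg, row(qimg)),
    `90` = split(qimg, col(qimg)),
    `45` = split(qimg, row(qimg) + col(qimg)),
    `135` = split(qimg, row(qimg) - col(qimg)),
    stop("unknown direction"))
  maxLen <- max(lengths(lines))
  counts <- matrix(0, nLevels, maxLen)
  for (ln in lines) {
    r <- rle(ifelse(is.na(ln), -1L, ln))
    keep <- r$values > 0
    if (any(keep)) {
      for (k in which(keep))
        counts[r$values[k], r$lengths[k]] <-
          counts[r$values[k], r$lengths[k]] + 1
    }
  }
  counts
}

glrlmStats <- function(R, nPixels) {
  Nr <- sum(R)
  jm <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  im <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  rj <- colSums(R); ri <- rowSums(R)
  c(glrlm_SRE = sum(R / jm^2) / Nr,
    glrlm_LRE = sum(R * jm^2) / Nr,
    glrlm_GLN = sum(ri^2) / Nr,
    glrlm_RLN = sum(rj^2) / Nr,
    glrlm_RP = Nr / nPixels,
    glrlm_LGLRE = sum(R / im^2) / Nr,
    glrlm_HGLRE = sum(R * im^2) / Nr,
    glrlm_SRLGLE = sum(R / (im^2 * jm^2)) / Nr,
    glrlm_SRHGLE = sum(R * im^2 / jm^2) / Nr,
    glrlm_LRLGLE = sum(R * jm^2 / im^2) / Nr,
    glrlm_LRHGLE = sum(R * im^2 * jm^2) / Nr)
}

#' Grey-level run-length features (11 features)
#'
#' Quantizes the ROI and counts maximal constant-level runs along the
#' four directions (runs are broken by the ROI boundary). The run
#' matrices are padded to a common maximum length and averaged over
#' directions before the 11 run-emphasis/nonuniformity features are
#' computed.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 11 features.
#' @export
glrlmFeatures <- function(image, roi, q = quantizationParams(),
                          directions = c("0", "45", "90", "135")) {
  roiMask <- if (is(roi, "ROIMask")) roi@mask else roi
  if (sum(roiMask) < 2L) stop("ROI must contain at least 2 pixels")
  qimg <- quantizeROI(image, roiMask, q)
  mats <- lapply(directions, glrlmMatrix, qimg = qimg, nLevels = q$nLevels)
  maxLen <- max(vapply(mats, ncol, integer(1)))
  mats <- lapply(mats, function(m) {
    if (ncol(m) < maxLen)
      m <- cbind(m, matrix(0, nrow(m), maxLen - ncol(m)))
    m
  })
  R <- Reduce(`+`, mats) / length(mats)
  glrlmStats(R, nPixels = sum(roiMask))
}

#' Textural features (30 features)
#'
#' The 19 co-occurrence plus 11 run-length features.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 30 features.
#' @export
texturalFeatures <- function(image, roi, q = quantizationParams()) {
  c(glcmFeatures(image, roi, q), glrlmFeatures(image, roi, q))
}
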