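#' Construct a phantom configuration
#'
#' Builds a [PhantomConfig-class] describing one synthetic
#' destruction--replenishment CEUS scan. Defaults describe a mid-size
#' tumour cross-section imaged at 10 frames/s for 48 frames with the
#' destruction pulse at frame 16.
#'
#' @param imageSize height/width in pixels.
#' @param nFrames,frameRate,destructionFrame acquisition timing.
#' @param phenotype `"P1"`, `"P2"` or `"P3"`.
#' @param vesselDensity target vessel-pixel fraction of the ROI.
#' @param nSeedsVessels,branchProbability vessel-tree growth controls.
#' @param replenishmentRateBeta replenishment rate \eqn{\beta} (1/s).
#' @param plateauAmplitudeA microbubble plateau amplitude.
#' @param backgroundLevel mean tissue intensity.
#' @param speckleScale speckle standard deviation (0 = noiseless).
#' @param speckleTemporalFrac fraction of the speckle variance that
#'   fluctuates between frames (default 0.4); the remainder is a static
#'   interference texture tied to the tissue scatterers.
#' @param textureGranularity speckle correlation length in pixels.
#' @param breathingPeriod,breathingShift breathing-artifact schedule.
#' @param rngSeed integer seed for the phantom geometry.
#' @return a [PhantomConfig-class] object.
#' @export
phantomConfig <- function(imageSize = c(96L, 96L), nFrames = 48L,
                          frameRate = 10, destructionFrame = 16L,
                          phenotype = "P1", vesselDensity = 0.10,
                          nSeedsVessels = 4L, branchProbability = 0.08,
                          replenishmentRateBeta = 0.8,
                          plateauAmplitudeA = 60, backgroundLevel = 20,
                          speckleScale = 6, speckleTemporalFrac = 0.4,
                          textureGranularity = 2,
                          breathingPeriod = 10L, breathingShift = 3L,
                          rngSeed = 1L) {
  new("PhantomConfig", imageSize = as.integer(imageSize),
      nFrames = as.integer(nFrames), frameRate = frameRate,
      destructionFrame = as.integer(destructionFrame),
      phenotype = phenotype, vesselDensity = vesselDensity,
      nSeedsVessels = as.integer(nSeedsVessels),
      branchProbability = branchProbability,
      replenishmentRateBeta = replenishmentRateBeta,
      plateauAmplitudeA = plateauAmplitudeA,
      backgroundLevel = backgroundLevel, speckleScale = speckleScale,
      speckleTemporalFrac = speckleTemporalFrac,
      textureGranularity = textureGranularity,
      breathingPeriod = as.integer(breathingPeriod),
      breathingShift = as.integer(breathingShift),
      rngSeed = as.integer(rngSeed))
}

# class parameter triplets for the three artificial tumour phenotypes:
# hypovascular/slow (P1), intermediate (P2), hypervascular/fast (P3)
.phenotypePresets <- list(
  P1 = list(vesselDensity = 0.08, replenishmentRateBeta = 0.5,
            backgroundLevel = 18),
  P2 = list(vesselDensity = 0.13, replenishmentRateBeta = 1.0,
            backgroundLevel = 22),
  P3 = list(vesselDensity = 0.20, replenishmentRateBeta = 1.8,
            backgroundLevel = 27))

#' Phenotype-preset phantom configuration
#'
#' Returns [phantomConfig()] with the class parameter triplet
#' (vascular density, replenishment rate, echogenicity) of one of the
#' three artificial tumour phenotypes.
#'
#' @param phenotype `"P1"`, `"P2"` or `"P3"`.
#' @param rngSeed integer seed.
#' @param ... overrides forwarded to [phantomConfig()].
#' @export
phenotypeConfig <- function(phenotype, rngSeed = 1L, ...) {
  preset <- .phenotypePresets[[phenotype]]
  if (is.null(preset)) stop("unknown phenotype: ", phenotype)
  args <- utils::modifyList(
    c(list(phenotype = phenotype, rngSeed = rngSeed), preset), list(...))
  do.call(phantomConfig, args)
}

# elliptical tumour ROI with seeded eccentricity and rotation
makeROI <- function(config) {
  h <- config@imageSize[1]; w <- config@imageSize[2]
  withSeed(config@rngSeed, {
    a <- 0.36 * w * runif(1, 0.9, 1.1)
    b <- 0.30 * h * runif(1, 0.9, 1.1)
    phi <- runif(1, 0, pi)
  })
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- cos(phi) * xx + sin(phi) * yy
  v <- -sin(phi) * xx + cos(phi) * yy
  (u / a)^2 + (v / b)^2 <= 1
}

dilate3x3 <- function(mask) mask | (neighbourCount(mask * 1L) > 0L)

# one seeded random walk (with optional dilation) added to the tree
growWalk <- function(skel, roi, start, maxLen, branchProb) {
  h <- nrow(roi); w <- ncol(roi)
  queue <- list(list(pos = start, theta = runif(1, 0, 2 * pi)))
  budget <- maxLen
  while (length(queue) && budget > 0L) {
    walker <- queue[[1]]; queue <- queue[-1]
    pos <- walker$pos; theta <- walker$theta
    while (budget > 0L) {
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 1 || r > h || c < 1 || c > w || !roi[r, c]) break
      skel[r, c] <- TRUE
      budget <- budget - 1L
      if (runif(1) < branchProb && length(queue) < 32L)
        queue[[length(queue) + 1L]] <-
          list(pos = pos, theta = theta + sample(c(-1, 1), 1) * pi / 2 +
                 rnorm(1, 0, 0.3))
      theta <- theta + rnorm(1, 0, 0.35)
      pos <- pos + c(sin(theta), cos(theta))
    }
  }
  skel
}

#' Generate a branching vessel tree phantom
#'
#' Grows branching curvilinear structures from `nSeedsVessels` seeded
#' root points by a random walk with branching, dilates main branches
#' to ~3 px width, and keeps adding walks (finally 1-px twigs) until the
#' vessel-pixel fraction of the ROI is within 10\% (relative) of
#' `vesselDensity`. Deterministic given `rngSeed`.
#'
#' @param config a [PhantomConfig-class].
#' @param roi optional logical ROI matrix; defaults to the phantom's
#'   elliptical tumour ROI.
#' @return logical matrix of vessel pixels (subset of the ROI).
#' @export
generateVesselTree <- function(config, roi = makeROI(config)) {
  target <- config@vesselDensity
  h <- config@imageSize[1]; w <- config@imageSize[2]
  if (target == 0) return(matrix(FALSE, h, w))
  area <- sum(roi)
  withSeed(config@rngSeed + 1L, {
    inner <- which(roi & !is.na(roi))
    mask <- matrix(FALSE, h, w)
    fraction <- 0
    iter <- 0L
    while (iter < 500L) {
      iter <- iter + 1L
      deficit <- target - fraction
      if (abs(deficit) / target <= 0.08) break
      if (deficit < 0) break  # slight overshoot within tolerance band
      idx <- sample(inner, 1L)
      start <- c((idx - 1L) %% h + 1L, (idx - 1L) %/% h + 1L)
      wide <- deficit > 0.35 * target && iter <= config@nSeedsVessels * 4L ||
        iter <= config@nSeedsVessels
      len <- if (wide) {
        max(12L, min(60L, round(deficit * area / 4)))
      } else {
        max(4L, min(40L, round(deficit * area)))
      }
      skel <- growWalk(matrix(FALSE, h, w), roi, start, len,
                       config@branchProbability)
      addition <- if (wide) dilate3x3(skel) & roi else skel & roi
      candidate <- mask | addition
      newFraction <- sum(candidate) / area
      if ((newFraction - target) / target > 0.08) next  # too big, redraw
      mask <- candidate
      fraction <- newFraction
    }
    if (abs(fraction - target) / target > 0.10)
      stop("vessel density target ", target,
           " unreachable (reached ", signif(fraction, 3), ")")
    mask
  })
}

# microbubble intensity time course for one scan: linear bolus ramp to
# the plateau A, destruction to ~0 at the destruction frame, then
# mono-exponential replenishment A (1 - exp(-beta t))
vesselTimeCourse <- function(config) {
  A <- config@plateauAmplitudeA
  fd <- config@destructionFrame
  f <- seq_len(config@nFrames)
  rampEnd <- max(2L, fd %/% 2L)
  pre <- A * pmin(1, (f - 1) / (rampEnd - 1))
  tsec <- (f - fd) / config@frameRate
  post <- A * (1 - exp(-config@replenishmentRateBeta * tsec))
  ifelse(f < fd, pre, ifelse(f == fd, 0, post))
}

#' Render a synthetic CEUS sequence from a vessel tree
#'
#' Produces the intensity stack: a speckle-textured tissue background
#' (smoothed exponential noise scaled to `speckleScale`, offset by the
#' phenotype's `backgroundLevel`) with the microbubble time course
#' added on vessel pixels, a destruction event at `destructionFrame`,
#' mono-exponential replenishment afterwards, and a globally shifted
#' frame every `breathingPeriod` frames (recorded in the ground truth).
#'
#' @param tree logical vessel mask from [generateVesselTree()].
#' @param config the [PhantomConfig-class] used to grow `tree`.
#' @param roi optional logical ROI matrix (defaults to the phantom ROI).
#' @param noiseSeed seed of the speckle realization; re-rendering with a
#'   different `noiseSeed` but the same `tree` yields a test/retest pair
#'   with identical ground-truth geometry.
#' @param scanID,mouseID,positionID,datasetID metadata labels.
#' @return `list(sequence = CEUSSequence, truth = GroundTruth)`.
#' @export
renderSequence <- function(tree, config, roi = makeROI(config),
                           noiseSeed = config@rngSeed + 101L,
                           scanID = "scan1", mouseID = "m1",
                           positionID = "p1", datasetID = "1") {
  stopifnot(all(dim(tree) == config@imageSize))
  h <- config@imageSize[1]; w <- config@imageSize[2]
  nT <- config@nFrames
  course <- vesselTimeCourse(config)
  bp <- config@breathingPeriod
  artifacts <- if (bp > 0L) seq.int(bp, nT, by = bp) else integer(0)
  frames <- array(0, dim = c(h, w, nT))
  speckleField <- function() {
    z <- gaussSmooth(matrix(rexp(h * w), h, w), config@textureGranularity)
    (z - mean(z)) / sd(z)
  }
  withSeed(noiseSeed, {
    wTemp <- config@speckleTemporalFrac
    z0 <- if (config@speckleScale > 0) speckleField() else NULL
    for (f in seq_len(nT)) {
      if (config@speckleScale > 0) {
        z <- sqrt(1 - wTemp^2) * z0 + wTemp * speckleField()
        img <- config@backgroundLevel + config@speckleScale * z
      } else {
        img <- matrix(config@backgroundLevel, h, w)
      }
      img[tree] <- img[tree] + course[f]
      if (f %in% artifacts)
        img <- shiftMatrix(img, config@breathingShift, 0L)
      frames[, , f] <- pmax(img, 0)
    }
  })
  seq <- new("CEUSSequence", frames = frames, frameRate = config@frameRate,
             destructionFrame = config@destructionFrame, scanID = scanID,
             mouseID = mouseID, modelLabel = config@phenotype,
             positionID = positionID, datasetID = datasetID)
  truth <- new("GroundTruth", trueROI = roi, trueVesselMask = tree,
               trueBeta = config@replenishmentRateBeta,
               trueRBV = sum(tree & roi) / sum(roi),
               trueNetworkLength = sum(skeletonize(tree)),
               trueArtifactFrames = as.integer(artifacts))
  list(sequence = seq, truth = truth)
}

#' Simulate a user's tumour delineation
#'
#' Perturbs the true ROI the way an independent observer would: a small
#' seeded boundary jitter (whole-mask shift of up to 1 px) followed by a
#' ~2 px dilation or erosion.
#'
#' @param roi logical matrix, the reference delineation.
#' @param mode `"none"`, `"dilate"` or `"erode"`.
#' @param seed integer jitter seed.
#' @param userID label stored in the result.
#' @return an [ROIMask-class].
#' @export
perturbROI <- function(roi, mode = c("none", "dilate", "erode"),
                       seed = 1L, userID = "user1") {
  mode <- match.arg(mode)
  m <- roi
  if (mode != "none") {
    withSeed(seed, {
      dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    })
    m <- shiftMatrix(m, dr, dc)
    brush <- EBImage::makeBrush(5L, shape = "disc")
    m <- if (mode == "dilate") {
      as.matrix(EBImage::imageData(EBImage::dilate(m * 1, brush))) > 0
    } else {
      as.matrix(EBImage::imageData(EBImage::erode(m * 1, brush))) > 0
    }
    if (!any(m)) m <- roi  # degenerate erosion: fall back
  }
  new("ROIMask", mask = m, userID = userID)
}

#' Generate a complete synthetic test/retest study
#'
#' Emulates the two-dataset study design: each animal is imaged at two
#' positions, and every position is acquired twice (test in dataset 1,
#' retest in dataset 2) by re-rendering the same phantom geometry with a
#' fresh speckle realization. Every scan carries three ROI delineations
#' (the true boundary plus a dilated and an eroded jittered variant).
#' The default sample sizes (5 + 5 + 4 animals, two positions each)
#' give 28 scans per dataset. Animal-level biological variability is
#' added as a seeded log-normal jitter on the class vascular density
#' and replenishment rate.
#'
#' @param nPerClass named integer vector of animals per phenotype.
#' @param seed integer master seed; the whole bundle is a pure function
#'   of `(seed, nPerClass, ...)`.
#' @param classJitterSD log-scale SD of the animal-level parameter
#'   jitter (default 0.10).
#' @param ... configuration overrides forwarded to [phenotypeConfig()]
#'   (e.g. `imageSize`, `speckleScale`).
#' @return a [CEUSStudy-class].
#' @export
generateStudy <- function(nPerClass = c(P1 = 5L, P2 = 5L, P3 = 4L),
                          seed = 1L, classJitterSD = 0.10, ...) {
  stopifnot(all(nPerClass >= 1L), !is.null(names(nPerClass)))
  seed <- as.integer(seed)
  scans <- list()
  manifest <- NULL
  mouseNo <- 0L
  scanNo <- 0L
  for (cls in names(nPerClass)) {
    for (a in seq_len(nPerClass[[cls]])) {
      mouseNo <- mouseNo + 1L
      mouseID <- sprintf("m%02d", mouseNo)
      preset <- .phenotypePresets[[cls]]
      jit <- withSeed(seed + 7919L * mouseNo, exp(rnorm(2, 0, classJitterSD)))
      for (p in 1:2) {
        scanNo <- scanNo + 1L
        scanSeed <- seed + 611L * scanNo
        cfg <- phenotypeConfig(
          cls, rngSeed = scanSeed,
          vesselDensity = min(0.6, preset$vesselDensity * jit[1]),
          replenishmentRateBeta = preset$replenishmentRateBeta * jit[2],
          ...)
        roi <- makeROI(cfg)
        tree <- generateVesselTree(cfg, roi)
        scanID <- sprintf("s%02d", scanNo)
        test <- renderSequence(tree, cfg, roi, noiseSeed = scanSeed + 11L,
                               scanID = scanID, mouseID = mouseID,
                               positionID = paste0("p", p), datasetID = "1")
        retest <- renderSequence(tree, cfg, roi, noiseSeed = scanSeed + 23L,
                                 scanID = scanID, mouseID = mouseID,
                                 positionID = paste0("p", p), datasetID = "2")
        rois <- list(
          perturbROI(roi, "none", userID = "user1"),
          perturbROI(roi, "dilate", seed = scanSeed + 31L, userID = "user2"),
          perturbROI(roi, "erode", seed = scanSeed + 37L, userID = "user3"))
        scans[[scanNo]] <- list(test = test$sequence,
                                retest = retest$sequence,
                                truth = test$truth, rois = rois)
        manifest <- rbind(manifest, data.frame(
          scanID = scanID, mouseID = mouseID, modelLabel = cls,
          positionID = paste0("p", p), stringsAsFactors = FALSE))
      }
    }
  }
  new("CEUSStudy", scans = scans, manifest = manifest)
}
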