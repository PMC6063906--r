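test_that("vessel tree generation is deterministic and hits its density", {
  cfg <- phenotypeConfig("P2", rngSeed = 9L)
  roi <- ceusRadiomics:::makeROI(cfg)
  t1 <- generateVesselTree(cfg, roi)
  t2 <- generateVesselTree(cfg, roi)
  expect_identical(t1, t2)
  frac <- sum(t1 & roi) / sum(roi)
  expect_gte(frac, 0.9 * cfg@vesselDensity)
  expect_lte(frac, 1.1 * cfg@vesselDensity)
  expect_true(all(t1 <= roi))  # vessels stay inside the ROI
})

test_that("density targets across the configured range are reachable", {
  for (d in c(0.05, 0.10, 0.20)) {
    cfg <- phantomConfig(vesselDensity = d, rngSeed = 3L)
    roi <- ceusRadiomics:::makeROI(cfg)
    frac <- sum(generateVesselTree(cfg, roi)) / sum(roi)
    expect_lte(abs(frac - d) / d, 0.10)
  }
})

test_that("zero vessel density yields an empty mask", {
  cfg <- phantomConfig(vesselDensity = 0, rngSeed = 1L)
  expect_false(any(generateVesselTree(cfg)))
})

test_that("noiseless render follows the replenishment model exactly", {
  # beta chosen so the half-life lands exactly on a frame boundary
  cfg <- phenotypeConfig("P1", rngSeed = 4L, speckleScale = 0,
                         nFrames = 160L, breathingPeriod = 0L,
                         replenishmentRateBeta = log(2) / 2)
  roi <- ceusRadiomics:::makeROI(cfg)
  tree <- generateVesselTree(cfg, roi)
  rs <- renderSequence(tree, cfg, roi)
  fr <- rs$sequence@frames
  fd <- cfg@destructionFrame
  vesselMean <- function(t) mean(fr[, , t][tree])
  bg <- cfg@backgroundLevel
  A <- cfg@plateauAmplitudeA
  beta <- cfg@replenishmentRateBeta
  # asymptote: far after destruction the vessel signal approaches A
  expect_lt(abs((vesselMean(160L) - bg) - A) / A, 0.01)
  # half-life: at t = ln(2)/beta past destruction the signal is A/2
  tHalf <- fd + log(2) / beta * cfg@frameRate
  stopifnot(abs(tHalf - round(tHalf)) < 1e-9)  # chosen to land on a frame
  expect_equal(vesselMean(round(tHalf)) - bg, A / 2, tolerance = 1e-9)
  # destruction drop by construction
  expect_lt(vesselMean(fd), vesselMean(fd - 1L))
})

test_that("breathing artifact frames follow the construction schedule", {
  fx <- fixtureScan()
  cfg <- fx$config
  expected <- seq.int(cfg@breathingPeriod, cfg@nFrames,
                      by = cfg@breathingPeriod)
  expect_identical(fx$truth@trueArtifactFrames, as.integer(expected))
})

test_that("ground-truth rBV matches the mask it was derived from", {
  fx <- fixtureScan()
  roi <- fx$truth@trueROI
  expect_equal(fx$truth@trueRBV,
               sum(fx$truth@trueVesselMask & roi) / sum(roi))
  expect_lte(abs(fx$truth@trueRBV - fx$config@vesselDensity) /
               fx$config@vesselDensity, 0.10)
})

test_that("a default study has the paper's design: 28 + 28 scans, 3 ROIs", {
  study <- fixtureStudy()
  expect_length(study@scans, 28L)
  expect_identical(as.integer(table(studyManifest(study)$modelLabel)),
                   c(10L, 10L, 8L))
  for (scan in study@scans) {
    expect_length(scan$rois, 3L)
    expect_s4_class(scan$test, "CEUSSequence")
    expect_s4_class(scan$retest, "CEUSSequence")
    expect_identical(scan$test@datasetID, "1")
    expect_identical(scan$retest@datasetID, "2")
    # test and retest share the phantom geometry, not the noise
    expect_false(identical(scan$test@frames, scan$retest@frames))
  }
  # each mouse appears at two positions
  m <- studyManifest(study)
  expect_true(all(table(m$mouseID) == 2L))
})

test_that("the study bundle is a pure function of its seed", {
  s1 <- generateStudy(nPerClass = c(P1 = 1L, P2 = 1L), seed = 77L,
                      imageSize = c(48L, 48L), nFrames = 24L,
                      destructionFrame = 9L)
  s2 <- generateStudy(nPerClass = c(P1 = 1L, P2 = 1L), seed = 77L,
                      imageSize = c(48L, 48L), nFrames = 24L,
                      destructionFrame = 9L)
  expect_identical(s1@scans[[2]]$test@frames, s2@scans[[2]]$test@frames)
  expect_identical(s1@scans[[1]]$rois[[3]]@mask, s2@scans[[1]]$rois[[3]]@mask)
  s3 <- generateStudy(nPerClass = c(P1 = 1L, P2 = 1L), seed = 78L,
                      imageSize = c(48L, 48L), nFrames = 24L,
                      destructionFrame = 9L)
  expect_false(identical(s1@scans[[1]]$test@frames,
                         s3@scans[[1]]$test@frames))
})

test_that("phenotype classes separate in ground-truth rBV and beta", {
  study <- fixtureStudy()
  m <- studyManifest(study)
  rbv <- vapply(study@scans, function(s) s$truth@trueRBV, numeric(1))
  beta <- vapply(study@scans, function(s) s$truth@trueBeta, numeric(1))
  rbvByClass <- split(rbv, m$modelLabel)
  betaByClass <- split(beta, m$modelLabel)
  expect_lt(max(rbvByClass$P1), min(rbvByClass$P3))
  expect_lt(median(rbvByClass$P1), median(rbvByClass$P2))
  expect_lt(median(betaByClass$P1), median(betaByClass$P2))
  expect_lt(median(betaByClass$P2), median(betaByClass$P3))
})

test_that("user ROI perturbations are valid single-component masks", {
  fx <- fixtureScan()
  roi <- fx$truth@trueROI
  d <- perturbROI(roi, "dilate", seed = 2L, userID = "user2")
  e <- perturbROI(roi, "erode", seed = 3L, userID = "user3")
  expect_gt(sum(maskMatrix(d)), sum(roi))
  expect_lt(sum(maskMatrix(e)), sum(roi))
  expect_identical(d@userID, "user2")
})
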