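test_that("adaptive smoothing leaves constants alone and damps impulses", {
  x <- matrix(4, 20, 20)
  expect_equal(adaptiveSmooth(x), x, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 10
  out <- adaptiveSmooth(imp)
  expect_lt(out[11, 11], 10)
  expect_identical(dim(out), dim(imp))
})

test_that("a static noiseless sequence has no artifact frames", {
  fr <- array(rep(matrix(3, 16, 16), 10), dim = c(16, 16, 10))
  seq <- new("CEUSSequence", frames = fr, frameRate = 10,
             destructionFrame = 5L, scanID = "s", mouseID = "m",
             modelLabel = "P1", positionID = "p1", datasetID = "1")
  expect_length(detectArtifactFrames(seq), 0L)
})

test_that("a single shifted frame is flagged exactly", {
  withr::with_seed(31L, base <- matrix(runif(32 * 32, 10, 20), 32, 32))
  fr <- array(rep(base, 12), dim = c(32, 32, 12))
  fr[, , 7] <- ceusRadiomics:::shiftMatrix(base, 4L, 0L)
  seq <- new("CEUSSequence", frames = fr, frameRate = 10,
             destructionFrame = 3L, scanID = "s", mouseID = "m",
             modelLabel = "P1", positionID = "p1", datasetID = "1")
  expect_identical(detectArtifactFrames(seq), 7L)
})

test_that("artifact detection recovers the construction schedule", {
  fx <- fixtureScan()
  den <- denoiseSequence(fx$seq)
  sm <- den
  for (t in seq_len(dim(den@frames)[3]))
    sm@frames[, , t] <- adaptiveSmooth(den@frames[, , t])
  flagged <- detectArtifactFrames(sm)
  truth <- fx$truth@trueArtifactFrames
  expect_true(all(truth %in% flagged))
  spurious <- setdiff(flagged, truth)
  expect_lte(length(spurious), ceiling(0.10 * dim(den@frames)[3]))
})

test_that("the motion projection isolates temporal change", {
  # static sequence: all-zero projection
  fr <- array(rep(matrix(5, 16, 16), 6), dim = c(16, 16, 6))
  seq <- new("CEUSSequence", frames = fr, frameRate = 10,
             destructionFrame = 3L, scanID = "s", mouseID = "m",
             modelLabel = "P1", positionID = "p1", datasetID = "1")
  roi <- new("ROIMask", mask = matrix(TRUE, 16, 16), userID = "user1")
  expect_true(all(motionMIP(seq, roi) == 0))
  # one pixel blinking once with amplitude a
  fr2 <- fr; fr2[8, 8, 4] <- 5 + 2.5
  seq2 <- seq; seq2@frames <- fr2
  mip <- motionMIP(seq2, roi)
  expect_equal(mip[8, 8], 2.5)
  expect_true(all(mip[-(8 + 16 * 7)] == 0))
  # excluding the blink frames removes the signal entirely
  mip2 <- motionMIP(seq2, roi, excluded = 4L)
  expect_true(all(mip2 == 0))
  # too few usable frames fail loudly
  expect_error(motionMIP(seq2, roi, excluded = 2:6), "usable frames")
})

test_that("binarization is empty on a zero projection and respects minSize", {
  roi <- new("ROIMask", mask = matrix(TRUE, 40, 40), userID = "user1")
  vm <- binarizeVessels(matrix(0, 40, 40), roi)
  expect_false(any(maskMatrix(vm)))
  # isolated blobs below minSize vanish, larger ones survive
  mip <- matrix(0, 40, 40)
  mip[5:6, 5:6] <- 10          # 4 px < minSize = 5
  mip[20:22, 20:22] <- 10      # 9 px
  vm2 <- binarizeVessels(mip, roi, minSize = 5L, offset = 1)
  expect_false(any(maskMatrix(vm2)[5:6, 5:6]))
  expect_true(all(maskMatrix(vm2)[20:22, 20:22]))
  # no surviving component is smaller than minSize
  sizes <- ceusRadiomics:::componentSizes(maskMatrix(vm2))
  expect_true(all(sizes >= 5L))
})

test_that("noiseless phantom segmentation recovers the true vessels", {
  fx <- fixtureScanNoiseless()
  vm <- segmentVessels(fx$seq, fx$roi)
  dice <- ceusRadiomics:::diceOverlap(maskMatrix(vm),
                                      fx$truth@trueVesselMask)
  expect_gte(dice, 0.8)
  # recall and precision individually
  tp <- sum(maskMatrix(vm) & fx$truth@trueVesselMask)
  expect_gte(tp / sum(fx$truth@trueVesselMask), 0.8)
  expect_gte(tp / sum(maskMatrix(vm)), 0.8)
})

test_that("segmentation quality degrades with increasing speckle", {
  dices <- vapply(c(0, 6, 18), function(sc) {
    cfg <- phenotypeConfig("P2", rngSeed = 5L, speckleScale = sc)
    roi <- ceusRadiomics:::makeROI(cfg)
    tree <- generateVesselTree(cfg, roi)
    rs <- renderSequence(tree, cfg, roi)
    vm <- segmentVessels(denoiseSequence(rs$sequence),
                         perturbROI(roi, "none"))
    ceusRadiomics:::diceOverlap(maskMatrix(vm), tree)
  }, numeric(1))
  expect_true(all(diff(dices) <= 0.02))  # sanity curve, small slack
})

test_that("replenishment fitting recovers noiseless kinetics to <1%", {
  cfg <- phenotypeConfig("P2", rngSeed = 6L, speckleScale = 0,
                         breathingPeriod = 0L, nFrames = 64L)
  roi <- ceusRadiomics:::makeROI(cfg)
  tree <- generateVesselTree(cfg, roi)
  rs <- renderSequence(tree, cfg, roi)
  fit <- fitReplenishment(rs$sequence, perturbROI(roi, "none"))
  expect_lt(abs(fit@beta - cfg@replenishmentRateBeta) /
              cfg@replenishmentRateBeta, 0.01)
  expect_equal(fit@velocity, fit@beta)  # beamWidth = 1 default
})

test_that("a flat post-destruction curve yields a degenerate flat fit", {
  fr <- array(rep(matrix(5, 16, 16), 20), dim = c(16, 16, 20))
  seq <- new("CEUSSequence", frames = fr, frameRate = 10,
             destructionFrame = 4L, scanID = "s", mouseID = "m",
             modelLabel = "P1", positionID = "p1", datasetID = "1")
  roi <- new("ROIMask", mask = matrix(TRUE, 16, 16), userID = "user1")
  fit <- fitReplenishment(seq, roi)
  expect_true(fit@A == 0 || fit@beta == 0)
  expect_lt(fit@rmse, 1e-8)
})

test_that("beta recovery on a noisy render stays within 15%", {
  fx <- fixtureScan()
  den <- denoiseSequence(fx$seq)
  vm <- segmentVessels(den, fx$roi)
  fit <- fitReplenishment(den, fx$roi, excluded = excludedFrames(vm))
  expect_lt(abs(fit@beta - fx$truth@trueBeta) / fx$truth@trueBeta, 0.15)
})

test_that("the fit uses seconds, not frame indices", {
  # same kinetics sampled at twice the frame rate gives the same beta
  cfg1 <- phenotypeConfig("P2", rngSeed = 8L, speckleScale = 0,
                          breathingPeriod = 0L, nFrames = 48L,
                          frameRate = 10)
  cfg2 <- phenotypeConfig("P2", rngSeed = 8L, speckleScale = 0,
                          breathingPeriod = 0L, nFrames = 96L,
                          frameRate = 20, destructionFrame = 32L)
  roi <- ceusRadiomics:::makeROI(cfg1)
  tree <- generateVesselTree(cfg1, roi)
  rmask <- perturbROI(roi, "none")
  f1 <- fitReplenishment(renderSequence(tree, cfg1, roi)$sequence, rmask)
  f2 <- fitReplenishment(renderSequence(tree, cfg2, roi)$sequence, rmask)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-3)
})
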