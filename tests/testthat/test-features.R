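test_that("first-order features match hand computations", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  f <- firstOrderFeatures(img, roi)
  expect_equal(unname(f["firstorder_mean"]), 2.5)
  expect_equal(unname(f["firstorder_median"]), 2.5)
  expect_equal(unname(f["firstorder_range"]), 3)
  expect_length(f, 14L)
  # constant ROI
  fc <- firstOrderFeatures(matrix(7, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(unname(fc["firstorder_median"]), 7)
  expect_equal(unname(fc["firstorder_range"]), 0)
  expect_equal(unname(fc["firstorder_variance"]), 0)
  expect_equal(unname(fc["firstorder_uniformity"]), 1)
  expect_error(firstOrderFeatures(img, matrix(c(TRUE, FALSE, FALSE, FALSE),
                                              2, 2)), "2 pixels")
})

test_that("co-occurrence features take their degenerate constant values", {
  f <- glcmFeatures(matrix(5, 4, 4), matrix(TRUE, 4, 4))
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_length(f, 19L)
})

test_that("checkerboard horizontal co-occurrence splits mass off-diagonal", {
  board <- outer(1:6, 1:6, function(r, c) (r + c) %% 2)
  roi <- matrix(TRUE, 6, 6)
  f <- glcmFeatures(board, roi, quantizationParams(2L), directions = "0")
  expect_equal(unname(f["glcm_energy"]), 0.5)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_max_probability"]), 0.5)
})

test_that("co-occurrence matrices are normalized for every direction", {
  withr::with_seed(41L, img <- matrix(sample(0:9, 49, TRUE), 7, 7))
  roi <- matrix(TRUE, 7, 7); roi[1, ] <- FALSE
  q <- quantizationParams(8L)
  qimg <- ceusRadiomics:::quantizeROI(img, roi, q)
  for (d in ceusRadiomics:::.glcmOffsets)
    expect_equal(sum(ceusRadiomics:::glcmMatrix(qimg, d, 8L)), 1)
})

test_that("run-length features match hand enumerations", {
  # single row [a,a,b,b,b]: runs {(a,2),(b,3)}, RLN = (1+1)/2 = 1
  img <- matrix(c(1, 1, 2, 2, 2), 1, 5)
  roi <- matrix(TRUE, 1, 5)
  f <- glrlmFeatures(img, roi, quantizationParams(2L), directions = "0")
  expect_equal(unname(f["glrlm_RLN"]), 1)
  expect_equal(unname(f["glrlm_GLN"]), 1)
  expect_equal(unname(f["glrlm_RP"]), 2 / 5)
  # constant row of length L: one run, RLN = 1, run percentage 1/L
  fc <- glrlmFeatures(matrix(3, 1, 8), matrix(TRUE, 1, 8),
                      quantizationParams(4L), directions = "0")
  expect_equal(unname(fc["glrlm_RLN"]), 1)
  expect_equal(unname(fc["glrlm_RP"]), 1 / 8)
})

test_that("texture features agree with exhaustive enumeration oracles", {
  withr::with_seed(43L, {
    for (rep in 1:4) {
      img <- matrix(sample(0:5, 36, TRUE) + rnorm(36, 0, 0.01), 6, 6)
      roi <- matrix(TRUE, 6, 6)
      if (rep > 2) roi[sample(36, 8)] <- FALSE  # ragged ROI
      q <- quantizationParams(6L)
      expect_equal(glcmFeatures(img, roi, q),
                   bruteGLCMFeatures(img, roi, 6L), tolerance = 1e-10)
      expect_equal(glrlmFeatures(img, roi, q),
                   bruteGLRLMFeatures(img, roi, 6L), tolerance = 1e-10)
      expect_equal(firstOrderFeatures(img, roi, q),
                   bruteFirstOrder(img, roi, 6L), tolerance = 1e-10)
    }
  })
})

test_that("vascular features of a single straight vessel are as drawn", {
  roi <- matrix(TRUE, 100, 100)
  vessel <- matrix(FALSE, 100, 100)
  vessel[50, 40:59] <- TRUE  # 1-px line of length 20
  fit <- new("ReplenishmentFit", I0 = 0, A = 1, beta = 0.5,
             velocity = 0.5, rmse = 0)
  f <- vascularFeatures(vessel, roi, fit)
  expect_equal(unname(f["vascular_n_vessels"]), 1)
  expect_lte(abs(unname(f["vascular_network_length"]) - 20), 2)
  expect_equal(unname(f["vascular_total_area"]), 20)
  expect_equal(unname(f["vascular_velocity"]), 0.5)
  expect_equal(unname(f["vascular_n_branch_points"]), 0)
  expect_length(f, 15L)
})

test_that("vessel mask equal to the ROI gives rBV 1 and distance 0", {
  roi <- matrix(FALSE, 30, 30); roi[8:22, 8:22] <- TRUE
  fit <- new("ReplenishmentFit", I0 = 0, A = 0, beta = 0, velocity = 0,
             rmse = 0)
  f <- vascularFeatures(roi, roi, fit)
  expect_equal(unname(f["vascular_rbv"]), 1)
  expect_equal(unname(f["vascular_dist_mean"]), 0)
  expect_equal(unname(f["vascular_rbv_periphery_core"]), 1)
})

test_that("an empty vessel mask returns the documented sentinels", {
  roi <- matrix(FALSE, 30, 30); roi[8:22, 8:22] <- TRUE
  fit <- new("ReplenishmentFit", I0 = 0, A = 0, beta = 0, velocity = 0,
             rmse = 0)
  f <- vascularFeatures(matrix(FALSE, 30, 30), roi, fit)
  expect_equal(unname(f["vascular_n_vessels"]), 0)
  expect_equal(unname(f["vascular_rbv"]), 0)
  expect_equal(unname(f["vascular_rbv_periphery_core"]), 0)
  expect_gt(unname(f["vascular_dist_mean"]), 0)  # ROI-internal max distance
  expect_true(all(is.finite(f)))
})

test_that("segmented rBV recovers the phantom ground truth within 10%", {
  fx <- fixtureScan()
  den <- denoiseSequence(fx$seq)
  vm <- segmentVessels(den, fx$roi)
  rbv <- sum(maskMatrix(vm)) / sum(maskMatrix(fx$roi))
  expect_lt(abs(rbv - fx$truth@trueRBV) / fx$truth@trueRBV, 0.10)
})

test_that("vascular area and network length grow with the vessel mask", {
  withr::with_seed(44L, {
    roi <- matrix(TRUE, 40, 40)
    small <- matrix(FALSE, 40, 40); small[20, 5:25] <- TRUE
    big <- small; big[10:12, 10:30] <- TRUE
    fit <- new("ReplenishmentFit", I0 = 0, A = 0, beta = 0,
               velocity = 0, rmse = 0)
    fs <- vascularFeatures(small, roi, fit)
    fb <- vascularFeatures(big, roi, fit)
    expect_gte(unname(fb["vascular_total_area"]),
               unname(fs["vascular_total_area"]))
    expect_gte(unname(fb["vascular_network_length"]),
               unname(fs["vascular_network_length"]))
  })
})

test_that("wavelet subband features number 176 and degenerate correctly", {
  withr::with_seed(45L, img <- matrix(runif(32 * 32, 10, 30), 32, 32))
  roi <- matrix(FALSE, 32, 32); roi[6:27, 6:27] <- TRUE
  f <- waveletSubbandFeatures(img, roi)
  expect_length(f, 176L)
  expect_true(all(is.finite(f)))
  expect_identical(sum(grepl("^waveletD_", names(f))), 44L)
  # constant image: detail subbands are flat, glcm energy degenerates to 1
  fcst <- waveletSubbandFeatures(matrix(4, 32, 32), roi)
  expect_equal(unname(fcst["waveletD_glcm_energy"]), 1)
})

test_that("the assembled vector has 235 features in the documented classes", {
  fx <- fixtureScan()
  fv <- extractFeatures(fx$seq, fx$roi)
  expect_length(fv, 235L)
  counts <- table(attr(fv, "featureClass"))
  expect_identical(as.integer(counts[c("first_order", "textural",
                                       "vascular", "wavelet")]),
                   c(14L, 30L, 15L, 176L))
  expect_true(all(is.finite(fv)))
  # determinism: a second run reproduces the vector exactly
  fv2 <- extractFeatures(fx$seq, fx$roi)
  expect_identical(fv, fv2)
})
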