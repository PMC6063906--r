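test_that("concordance correlation matches its closed form", {
  expect_equal(concordanceCC(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(concordanceCC(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(concordanceCC(c(2, 2, 2), c(5, 5, 5)), 0)
  expect_equal(concordanceCC(c(4, 4), c(4, 4)), 1)  # identical constants
  withr::with_seed(51L, {
    for (rep in 1:5) {
      x <- rnorm(8); y <- 0.5 * x + rnorm(8, 0, 0.3)
      expect_equal(concordanceCC(x, y), bruteCCC(x, y), tolerance = 1e-12)
    }
  })
  expect_error(concordanceCC(1:3, 1:4))
})

test_that("normalized dynamic range behaves as specified", {
  expect_equal(normalizedDynamicRange(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(normalizedDynamicRange(c(0, 1), c(1, 0)), 0)
  expect_equal(normalizedDynamicRange(c(3, 3), c(3, 3)), 0)  # R = 0
  # halving repeat differences strictly increases DR at fixed range
  test <- c(0, 2, 10); retest <- c(1, 3, 10)
  half <- c(0.5, 2.5, 10)
  expect_gt(normalizedDynamicRange(test, half),
            normalizedDynamicRange(test, retest))
})

test_that("the Quade user-independence test matches its definition", {
  withr::with_seed(52L, {
    m <- matrix(rnorm(24), 8, 3)
    expect_equal(quadeUserIndependence(m), bruteQuadeP(m),
                 tolerance = 1e-10)
    # block permutation invariance
    expect_equal(quadeUserIndependence(m[sample(8), ]),
                 quadeUserIndependence(m))
    # identical columns: no user effect
    same <- matrix(rnorm(10), 10, 3)[, c(1, 1, 1)]
    expect_equal(quadeUserIndependence(same), 1)
    # one user systematically shifted
    shifted <- matrix(rnorm(30), 10, 3)
    shifted[, 2] <- shifted[, 2] + 50
    expect_lt(quadeUserIndependence(shifted), 0.05)
  })
})

test_that("Kruskal-Wallis power statistic matches the tie-corrected form", {
  withr::with_seed(53L, {
    for (rep in 1:5) {
      v <- c(rnorm(4), rnorm(4, 1), rnorm(4, 2))
      v[1:2] <- v[3]  # introduce ties
      g <- rep(c("a", "b", "c"), each = 4)
      expect_equal(kruskalWallisPower(v, g), bruteKruskalP(v, g),
                   tolerance = 1e-12)
    }
  })
  # fully separated groups of two: H is maximal for n = 6,
  # H = (12/42) * 16 = 32/7, p = P(chi2_2 > 32/7) ~ 0.102
  v <- c(1, 2, 11, 12, 21, 22)
  g <- rep(1:3, each = 2)
  expect_equal(kruskalWallisPower(v, g),
               pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(kruskalWallisPower(v, g), 0.11)
  # jointly permuting observations leaves the statistic unchanged
  withr::with_seed(54L, idx <- sample(6))
  expect_equal(kruskalWallisPower(v[idx], g[idx]),
               kruskalWallisPower(v, g))
})

test_that("the Kruskal-Wallis ranking holds its nominal type-I error", {
  withr::with_seed(55L, {
    p <- replicate(1000, {
      kruskalWallisPower(rnorm(15), rep(1:3, each = 5))
    })
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("rank aggregation averages ranks with the documented tie-break", {
  rk <- data.frame(feature = c("a", "b", "c", "d"),
                   rank_ccc = c(1L, 4L, 2L, 3L),
                   rank_dr = c(2L, 3L, 1L, 4L),
                   rank_user = c(3L, 2L, 4L, 1L),
                   rank_power = c(4L, 1L, 3L, 2L))
  agg <- aggregateRankings(rk)
  # all mean ranks tie at 2.5: order decided by rank_ccc, then name
  expect_identical(agg$final_rank, c(1L, 4L, 2L, 3L))
  expect_setequal(agg$final_rank, 1:4)
  rk2 <- data.frame(feature = c("x", "y"),
                    rank_ccc = c(1L, 2L), rank_dr = c(1L, 2L),
                    rank_user = c(1L, 2L), rank_power = c(1L, 2L))
  expect_identical(aggregateRankings(rk2)$final_rank, c(1L, 2L))
})

test_that("ranking table columns are permutations of 1..N", {
  eng <- engineeredFeatureStudy(seed = 101L)
  rk <- rankFeatures(eng$fs)
  n <- nrow(rk)
  for (col in c("rank_ccc", "rank_dr", "rank_user", "rank_power",
                "final_rank"))
    expect_setequal(rk[[col]], seq_len(n))
})

test_that("signature selection recovers engineered per-class features", {
  eng <- engineeredFeatureStudy(seed = 101L)
  rk <- rankFeatures(eng$fs)
  sig <- selectSignature(rk, featureMatrix(eng$fs, "user1", "1"))
  expect_setequal(signatureFeatures(sig), eng$designated)
  expect_identical(signatureClasses(sig),
                   c("first_order", "textural", "vascular", "wavelet"))
  off <- abs(signatureCor(sig)); diag(off) <- 0
  expect_lte(max(off), 0.75)
})

test_that("a perfectly correlated duplicate forces a replacement", {
  eng <- engineeredFeatureStudy(seed = 102L)
  fs <- eng$fs
  mat <- SummarizedExperiment::assay(fs)
  # make the top textural feature a duplicate of the first-order one:
  # its class selection must then move on to another feature
  mat["glcm_designated", ] <- mat["firstorder_designated", ]
  fs2 <- radiomicFeatureSet(mat,
                            as.data.frame(SummarizedExperiment::colData(fs)))
  rk <- rankFeatures(fs2)
  sig <- selectSignature(rk, featureMatrix(fs2, "user1", "1"))
  expect_true("firstorder_designated" %in% signatureFeatures(sig) ||
                "glcm_designated" %in% signatureFeatures(sig))
  expect_false(all(c("firstorder_designated", "glcm_designated") %in%
                     signatureFeatures(sig)))
  off <- abs(signatureCor(sig)); diag(off) <- 0
  expect_lte(max(off), 0.75)
})

test_that("selection is deterministic given the feature tables", {
  eng <- engineeredFeatureStudy(seed = 103L)
  rk1 <- rankFeatures(eng$fs)
  rk2 <- rankFeatures(eng$fs)
  expect_identical(rk1, rk2)
  s1 <- selectSignature(rk1, featureMatrix(eng$fs, "user1", "1"))
  s2 <- selectSignature(rk2, featureMatrix(eng$fs, "user1", "1"))
  expect_identical(signatureFeatures(s1), signatureFeatures(s2))
})
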