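#' Concordance correlation coefficient
#'
#' Lin's agreement measure between paired measurements:
#' \eqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with
#' moments normalized by `1/n`. Two identical constant vectors give 1
#' by convention; constant vectors with different values give 0.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a value in `[-1, 1]`.
#' @export
concordanceCC <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)
  2 * sxy / denom
}

#' Normalized dynamic range
#'
#' Biological spread of a feature relative to its test--retest
#' variability: \eqn{DR = \frac{1}{n}\sum_i (1 - |t_i - r_i| / R)} with
#' `R` the range of the pooled test and retest values. A feature whose
#' repeat differences are small compared to its range scores near 1.
#' `R = 0` (no biological range at all) is defined as `DR = 0`.
#'
#' @param test,retest numeric vectors of equal length.
#' @return a value in `[0, 1]`.
#' @export
normalizedDynamicRange <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  pooled <- c(test, retest)
  R <- max(pooled) - min(pooled)
  if (R == 0) return(0)
  dr <- mean(1 - abs(test - retest) / R)
  min(max(dr, 0), 1)
}

#' Quade test for user independence
#'
#' Rank-based blocked test of whether the three delineating users
#' produce systematically different feature values; scans are blocks,
#' users are treatments. A high p-value ranks the feature as more
#' user-independent. Degenerate tables whose blocks are all internally
#' constant return `p = 1` by convention.
#'
#' @param values numeric matrix, scans in rows, users in columns.
#' @return the Quade test p-value.
#' @export
quadeUserIndependence <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3L, ncol(values) >= 2L)
  ranges <- apply(values, 1, function(r) max(r) - min(r))
  if (all(ranges == 0)) return(1)
  p <- tryCatch(stats::quade.test(values)$p.value, error = function(e) NA_real_)
  if (!is.finite(p)) 1 else p
}

#' Kruskal-Wallis discriminative power
#'
#' Tie-corrected Kruskal-Wallis H test of a feature across the tumour
#' model groups; a lower p-value means higher discriminative power.
#'
#' @param values numeric vector.
#' @param labels group labels (same length).
#' @return the chi-square approximation p-value.
#' @export
kruskalWallisPower <- function(values, labels) {
  labels <- as.factor(labels)
  stopifnot(length(values) == length(labels))
  if (any(table(labels) < 2L)) stop("each group needs >= 2 observations")
  if (max(values) == min(values)) return(1)   # constant feature
  stats::kruskal.test(values, labels)$p.value
}

# deterministic 1..N ranking: best first by `primary` (already oriented
# so that smaller is better), ties broken by feature name
orientedRank <- function(primary, featureNames) {
  ord <- order(primary, featureNames)
  r <- integer(length(primary))
  r[ord] <- seq_along(primary)
  r
}

#' Compute the four-criterion feature ranking table
#'
#' For every feature of the study table, computes the four selection
#' statistics and ranks: test/retest stability (concordance
#' correlation coefficient between dataset 1 and dataset 2 per user,
#' averaged over users; ranked high to low), normalized dynamic range
#' (averaged over users; high to low), user independence (Quade test
#' across the three delineations on the combined datasets; p ranked
#' high to low), and discriminative power (Kruskal-Wallis p across
#' tumour models on dataset 1; low to high). The final rank is the
#' ascending order of the mean of the four ranks, with ties broken by
#' the stability rank and then the feature name.
#'
#' @param fs a [RadiomicFeatureSet-class] covering both datasets and
#'   all users.
#' @param kwDataset dataset used for the discriminative-power ranking
#'   (default `"1"`).
#' @return a data.frame (one row per feature) with the statistics, the
#'   four rank columns, and `final_rank` -- each rank column a
#'   permutation of `1..nFeatures`.
#' @export
rankFeatures <- function(fs, kwDataset = "1") {
  cd <- SummarizedExperiment::colData(fs)
  users <- sort(unique(cd$userID))
  featureNames <- rownames(fs)
  perUser1 <- lapply(users, function(u) featureMatrix(fs, u, "1"))
  perUser2 <- lapply(users, function(u) featureMatrix(fs, u, "2"))
  names(perUser1) <- names(perUser2) <- users
  n <- length(featureNames)
  ccc <- dr <- quadeP <- kwP <- numeric(n)
  # group labels aligned with featureMatrix's scan ordering
  ord <- order(unique(cd$scanID))
  scanModels <- cd$modelLabel[match(unique(cd$scanID), cd$scanID)][ord]
  kwUser <- users[1]
  for (k in seq_len(n)) {
    cccU <- vapply(users, function(u)
      concordanceCC(perUser1[[u]][, k], perUser2[[u]][, k]), numeric(1))
    drU <- vapply(users, function(u)
      normalizedDynamicRange(perUser1[[u]][, k], perUser2[[u]][, k]),
      numeric(1))
    ccc[k] <- mean(cccU)
    dr[k] <- mean(drU)
    combined <- vapply(users, function(u)
      c(perUser1[[u]][, k], perUser2[[u]][, k]),
      numeric(2L * nrow(perUser1[[1]])))
    quadeP[k] <- quadeUserIndependence(combined)
    kwVals <- if (kwDataset == "1") perUser1[[kwUser]][, k] else
      perUser2[[kwUser]][, k]
    kwP[k] <- kruskalWallisPower(kwVals, scanModels)
  }
  rankCCC <- orientedRank(-ccc, featureNames)
  rankDR <- orientedRank(-dr, featureNames)
  rankUser <- orientedRank(-quadeP, featureNames)
  rankPower <- orientedRank(kwP, featureNames)
  score <- (rankCCC + rankDR + rankUser + rankPower) / 4
  finalOrd <- order(score, rankCCC, featureNames)
  finalRank <- integer(n); finalRank[finalOrd] <- seq_len(n)
  data.frame(feature = featureNames,
             featureClass = featureClassOf(featureNames),
             ccc = ccc, dynamic_range = dr, quade_p = quadeP, kw_p = kwP,
             rank_ccc = rankCCC, rank_dr = rankDR, rank_user = rankUser,
             rank_power = rankPower, final_rank = finalRank,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate four rank columns into a final ranking
#'
#' The final score of a feature is the unweighted mean of its four
#' criterion ranks; features are ranked by ascending score with ties
#' broken by the stability (CCC) rank and then the feature name.
#'
#' @param ranking a data.frame with columns `feature`, `rank_ccc`,
#'   `rank_dr`, `rank_user`, `rank_power`.
#' @return the data.frame with a recomputed `final_rank` column.
#' @export
aggregateRankings <- function(ranking) {
  score <- (ranking$rank_ccc + ranking$rank_dr + ranking$rank_user +
              ranking$rank_power) / 4
  ord <- order(score, ranking$rank_ccc, ranking$feature)
  ranking$final_rank <- integer(nrow(ranking))
  ranking$final_rank[ord] <- seq_len(nrow(ranking))
  ranking
}

#' Select the four-feature radiomic signature
#'
#' Picks the best final-ranked feature of each imaging biomarker class,
#' then prunes redundancy: while any pair of selected features has
#' Pearson `|r| >` `rMax` on the reference values, the worse-ranked
#' member of the most-correlated offending pair is replaced by the next
#' feature of its class, until the four features are pairwise
#' uncorrelated at the threshold.
#'
#' @param ranking the table from [rankFeatures()].
#' @param values numeric matrix (samples x features, named columns)
#'   used for the correlation analysis -- conventionally the user-1,
#'   dataset-1 values.
#' @param rMax correlation threshold (default 0.75).
#' @return a [RadiomicSignature-class].
#' @export
selectSignature <- function(ranking, values, rMax = 0.75) {
  classes <- c("first_order", "textural", "vascular", "wavelet")
  candidates <- lapply(classes, function(cl) {
    sub <- ranking[ranking$featureClass == cl, ]
    sub$feature[order(sub$final_rank)]
  })
  names(candidates) <- classes
  pick <- vapply(candidates, `[`, character(1), 1L)
  pos <- setNames(rep(1L, 4L), classes)
  finalRankOf <- setNames(ranking$final_rank, ranking$feature)
  corOf <- function(features) {
    cm <- suppressWarnings(cor(values[, features, drop = FALSE]))
    cm[!is.finite(cm)] <- 0      # constant feature: no evidence of redundancy
    diag(cm) <- 1
    cm
  }
  for (iter in seq_len(1000L)) {
    cm <- corOf(pick)
    off <- abs(cm); diag(off) <- 0
    if (max(off) <= rMax) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- classes[c(worst[1], worst[2])]
    loser <- pair[which.max(finalRankOf[pick[pair]])]
    pos[loser] <- pos[loser] + 1L
    if (pos[loser] > length(candidates[[loser]]))
      stop("biomarker class '", loser,
           "' exhausted without satisfying the correlation constraint")
    pick[loser] <- candidates[[loser]][pos[loser]]
  }
  cm <- corOf(pick)
  new("RadiomicSignature", features = unname(pick), classes = classes,
      corMatrix = cm)
}
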