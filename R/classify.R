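#' Column-wise z-score standardization
#'
#' Transforms each column to zero mean and unit standard deviation;
#' constant columns become all zeros (documented convention). The
#' transform is idempotent.
#'
#' @param x numeric matrix (samples x features).
#' @return standardized matrix of the same shape.
#' @export
zscoreTable <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  out <- sweep(x, 2, mu)
  ok <- s > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, s[ok], "/")
  out[, !ok] <- 0
  out
}

#' Wilson score confidence interval for a proportion
#'
#' Interval obtained by inverting the binomial score test:
#' centre \eqn{(\hat p + z^2/2n) / (1 + z^2/n)}, half-width
#' \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n)}.
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
wilsonInterval <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1L, successes >= 0, successes <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# seeded stratified fold assignment; falls back to plain folds when a
# class has fewer members than folds
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  folds <- integer(n)
  withSeed(seed, {
    if (any(table(labels) < k)) {
      folds <- sample(rep_len(seq_len(k), n))
    } else {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
  })
  folds
}

#' Cross-validated linear SVM classification
#'
#' Stratified k-fold cross-validation of a linear-kernel soft-margin
#' support vector machine (C = 1, one-vs-one multiclass). Held-out
#' predictions are pooled into a single confusion matrix; the accuracy
#' is the pooled fraction of correct predictions with its 95\% Wilson
#' score interval.
#'
#' @param x numeric matrix (samples x features), e.g. the z-scored
#'   signature columns.
#' @param labels class labels.
#' @param k number of folds (default 4).
#' @param seed fold-assignment seed.
#' @param cost SVM regularization constant (default 1).
#' @return a [ClassificationResult-class].
#' @export
cvSVM <- function(x, labels, k = 4L, seed = 1L, cost = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  folds <- stratifiedFolds(labels, k, seed)
  pred <- factor(rep(NA_character_, length(labels)),
                 levels = levels(labels))
  for (f in seq_len(k)) {
    train <- folds != f
    fit <- e1071::svm(x[train, , drop = FALSE], labels[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred[!train] <- predict(fit, x[!train, , drop = FALSE])
  }
  confusion <- table(true = labels, predicted = pred)
  acc <- sum(diag(confusion)) / length(labels)
  ci <- wilsonInterval(sum(diag(confusion)), length(labels))
  new("ClassificationResult", confusion = unclass(confusion),
      accuracy = acc, wilsonCI = unname(ci), folds = folds)
}

#' Agglomerative hierarchical clustering of the feature table
#'
#' Euclidean-distance, average-linkage (UPGMA) clustering of the
#' samples, with the tree cut into `nClusters` groups.
#'
#' @param x numeric matrix (samples x features), typically the full
#'   z-scored 235-feature table.
#' @param nClusters number of clusters to cut (default 3).
#' @return a [ClusterResult-class] (enrichment table empty until
#'   [clusterEnrichment()] is run).
#' @export
hierarchicalCluster <- function(x, nClusters = 3L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= nClusters)
  tree <- hclust(dist(x, method = "euclidean"), method = "average")
  labels <- cutree(tree, k = nClusters)
  new("ClusterResult", tree = tree, labels = as.integer(labels),
      enrichment = data.frame())
}

#' Exact multinomial test
#'
#' Probability, under multinomial sampling with probabilities `prob`,
#' of an outcome at most as probable as the observed counts (sum of
#' `dmultinom` over all compositions with probability <= the observed
#' one, within numerical tolerance).
#'
#' @param counts observed category counts.
#' @param prob expected category probabilities (same length).
#' @return the exact p-value.
#' @export
exactMultinomialTest <- function(counts, prob) {
  stopifnot(length(counts) == length(prob), all(counts >= 0))
  prob <- prob / sum(prob)
  n <- sum(counts)
  if (n == 0) return(1)
  pObs <- dmultinom(counts, prob = prob)
  kcat <- length(counts)
  total <- 0
  recurse <- function(prefix, remaining, slot) {
    if (slot == kcat) {
      p <- dmultinom(c(prefix, remaining), prob = prob)
      if (p <= pObs * (1 + 1e-10)) total <<- total + p
      return(invisible(NULL))
    }
    for (v in 0:remaining) recurse(c(prefix, v), remaining - v, slot + 1L)
  }
  recurse(integer(0), n, 1L)
  min(total, 1)
}

#' Cluster composition enrichment tests
#'
#' For every cluster, an exact multinomial test of its tumour-model
#' composition against the overall model frequencies, followed by
#' per-model exact binomial post-hoc tests of over/under-representation
#' with Bonferroni correction over all (cluster, model) post-hoc tests.
#'
#' @param clusterLabels integer cluster assignment per sample.
#' @param modelLabels tumour model per sample.
#' @return data.frame with one row per (cluster, model): observed
#'   count, cluster size, expected proportion, the cluster-level
#'   multinomial p, the raw post-hoc binomial p, and the
#'   Bonferroni-adjusted p.
#' @export
clusterEnrichment <- function(clusterLabels, modelLabels) {
  stopifnot(length(clusterLabels) == length(modelLabels))
  models <- sort(unique(modelLabels))
  prob <- as.numeric(table(factor(modelLabels, levels = models))) /
    length(modelLabels)
  clusters <- sort(unique(clusterLabels))
  rows <- list()
  for (cl in clusters) {
    inCl <- clusterLabels == cl
    if (!any(inCl)) next
    counts <- as.numeric(table(factor(modelLabels[inCl], levels = models)))
    pMulti <- exactMultinomialTest(counts, prob)
    for (m in seq_along(models)) {
      pBin <- binom.test(counts[m], sum(counts), p = prob[m])$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, model = models[m], observed = counts[m],
        clusterSize = sum(counts), expectedProp = prob[m],
        p_multinomial = pMulti, p_posthoc = pBin,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_posthoc * nrow(out))  # Bonferroni
  out
}

#' Pairwise group differences (Tukey HSD)
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference
#' post-hoc test on all group pairs.
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @return data.frame with the pair, mean difference and adjusted
#'   p-value.
#' @export
groupDifferencePosthoc <- function(values, labels) {
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop("each group needs >= 2 observations")
  fit <- aov(values ~ labels)
  tk <- TukeyHSD(fit)$labels
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adjusted = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
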