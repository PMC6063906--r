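# Independent brute-force reference implementations used to verify the
# package's statistics and texture features on small inputs. These are
# deliberately written as naive scalar loops, separate from the package
# code paths.

bruteFirstOrder <- function(image, roiMask, nLevels = 32L) {
  x <- sort(image[roiMask])  # sorting irrelevant; emphasises independence
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lo <- x[1]; hi <- x[n]
  bins <- if (hi == lo) rep(1L, n) else
    pmin(floor((x - lo) / (hi - lo) * nLevels) + 1L, nLevels)
  p <- as.numeric(table(factor(bins, levels = 1:nLevels))) / n
  pz <- p[p > 0]
  c(firstorder_energy = sum(x^2),
    firstorder_entropy = -sum(pz * log2(pz)),
    firstorder_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_maximum = hi,
    firstorder_mean = mu,
    firstorder_mad = sum(abs(x - mu)) / n,
    firstorder_median = unname(quantile(x, 0.5, type = 7)),
    firstorder_minimum = lo,
    firstorder_range = hi - lo,
    firstorder_rms = sqrt(sum(x^2) / n),
    firstorder_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_sd = sqrt(m2),
    firstorder_uniformity = sum(p^2),
    firstorder_variance = m2)
}

# quantization identical by definition (min-max, nLevels bins)
bruteQuantize <- function(image, roiMask, nLevels) {
  vals <- image[roiMask]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    if (!roiMask[r, c]) next
    q[r, c] <- if (hi == lo) 1L else
      min(floor((image[r, c] - lo) / (hi - lo) * nLevels) + 1L, nLevels)
  }
  q
}

# co-occurrence matrix by exhaustive pixel-pair enumeration
bruteGLCMMatrix <- function(qimg, dr, dc, nLevels) {
  P <- matrix(0, nLevels, nLevels)
  for (r in seq_len(nrow(qimg))) for (c in seq_len(ncol(qimg))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(qimg) || c2 < 1 || c2 > ncol(qimg)) next
    i <- qimg[r, c]; j <- qimg[r2, c2]
    if (is.na(i) || is.na(j)) next
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  if (sum(P) > 0) P / sum(P) else P
}

bruteGLCMFeatures <- function(image, roiMask, nLevels = 32L,
                              directions = c("0", "45", "90", "135")) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  qimg <- bruteQuantize(image, roiMask, nLevels)
  Ps <- lapply(offs[directions], function(d)
    bruteGLCMMatrix(qimg, d[1], d[2], nLevels))
  P <- Reduce(`+`, Ps) / length(Ps)
  L <- nLevels
  px <- numeric(L)
  for (i in 1:L) px[i] <- sum(P[i, ])
  mux <- 0; for (i in 1:L) mux <- mux + i * px[i]
  sx2 <- 0; for (i in 1:L) sx2 <- sx2 + (i - mux)^2 * px[i]
  feats <- c(autocorrelation = 0, cluster_prominence = 0,
             cluster_shade = 0, contrast = 0, dissimilarity = 0,
             energy = 0, entropy = 0, homogeneity = 0, idmn = 0,
             variance = 0, inverse_variance = 0)
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    feats["autocorrelation"] <- feats["autocorrelation"] + i * j * p
    feats["cluster_prominence"] <-
      feats["cluster_prominence"] + (i + j - 2 * mux)^4 * p
    feats["cluster_shade"] <-
      feats["cluster_shade"] + (i + j - 2 * mux)^3 * p
    feats["contrast"] <- feats["contrast"] + (i - j)^2 * p
    feats["dissimilarity"] <- feats["dissimilarity"] + abs(i - j) * p
    feats["energy"] <- feats["energy"] + p^2
    if (p > 0) feats["entropy"] <- feats["entropy"] - p * log2(p)
    feats["homogeneity"] <- feats["homogeneity"] + p / (1 + (i - j)^2)
    feats["idmn"] <- feats["idmn"] + p / (1 + (i - j)^2 / L^2)
    feats["variance"] <- feats["variance"] + (i - mux)^2 * p
    if (i != j)
      feats["inverse_variance"] <-
        feats["inverse_variance"] + p / (i - j)^2
    if (p > 0 && px[i] * px[j] > 0)
      HXY1 <- HXY1 - p * log2(px[i] * px[j])
    if (px[i] * px[j] > 0)
      HXY2 <- HXY2 - px[i] * px[j] * log2(px[i] * px[j])
  }
  pdiff <- numeric(L); psum <- numeric(2 * L)
  for (i in 1:L) for (j in 1:L) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
    psum[i + j] <- psum[i + j] + P[i, j]
  }
  de <- 0; for (p in pdiff) if (p > 0) de <- de - p * log2(p)
  se <- 0; for (p in psum) if (p > 0) se <- se - p * log2(p)
  sa <- 0; for (kk in 2:(2 * L)) sa <- sa + kk * psum[kk]
  sv <- 0; for (kk in 2:(2 * L)) sv <- sv + (kk - sa)^2 * psum[kk]
  HX <- 0; for (p in px) if (p > 0) HX <- HX - p * log2(p)
  HXY <- unname(feats["entropy"])
  corr <- if (sx2 > 0) (unname(feats["autocorrelation"]) - mux^2) / sx2 else 1
  c(glcm_autocorrelation = unname(feats["autocorrelation"]),
    glcm_cluster_prominence = unname(feats["cluster_prominence"]),
    glcm_cluster_shade = unname(feats["cluster_shade"]),
    glcm_contrast = unname(feats["contrast"]),
    glcm_correlation = corr,
    glcm_difference_entropy = de,
    glcm_dissimilarity = unname(feats["dissimilarity"]),
    glcm_energy = unname(feats["energy"]),
    glcm_entropy = HXY,
    glcm_homogeneity = unname(feats["homogeneity"]),
    glcm_imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    glcm_imc2 = sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0)),
    glcm_idmn = unname(feats["idmn"]),
    glcm_max_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = se,
    glcm_sum_variance = sv,
    glcm_variance = unname(feats["variance"]),
    glcm_inverse_variance = unname(feats["inverse_variance"]))
}

# run enumeration by explicit line walking
bruteGLRLMMatrix <- function(qimg, direction, nLevels) {
  nr <- nrow(qimg); nc <- ncol(qimg)
  step <- switch(direction, `0` = c(0, 1), `90` = c(1, 0),
                 `45` = c(-1, 1), `135` = c(1, 1))
  starts <- list()
  for (r in 1:nr) for (c in 1:nc) {
    rp <- r - step[1]; cp <- c - step[2]
    if (rp < 1 || rp > nr || cp < 1 || cp > nc)
      starts[[length(starts) + 1L]] <- c(r, c)
  }
  counts <- matrix(0, nLevels, max(nr, nc))
  for (s in starts) {
    r <- s[1]; c <- s[2]
    runLevel <- NA_integer_; runLen <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- qimg[r, c]
      if (!is.na(v) && !is.na(runLevel) && v == runLevel) {
        runLen <- runLen + 1L
      } else {
        if (!is.na(runLevel))
          counts[runLevel, runLen] <- counts[runLevel, runLen] + 1
        runLevel <- v; runLen <- 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(runLevel))
      counts[runLevel, runLen] <- counts[runLevel, runLen] + 1
  }
  counts
}

bruteGLRLMFeatures <- function(image, roiMask, nLevels = 32L,
                               directions = c("0", "45", "90", "135")) {
  qimg <- bruteQuantize(image, roiMask, nLevels)
  mats <- lapply(directions, bruteGLRLMMatrix, qimg = qimg,
                 nLevels = nLevels)
  width <- max(vapply(mats, ncol, integer(1)))
  R <- matrix(0, nLevels, width)
  for (m in mats) R[, seq_len(ncol(m))] <- R[, seq_len(ncol(m))] + m
  R <- R / length(mats)
  Nr <- sum(R); Np <- sum(roiMask)
  out <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = Nr / Np, LGLRE = 0,
           HGLRE = 0, SRLGLE = 0, SRHGLE = 0, LRLGLE = 0, LRHGLE = 0)
  for (i in seq_len(nrow(R))) {
    out["GLN"] <- out["GLN"] + sum(R[i, ])^2
    for (j in seq_len(ncol(R))) {
      v <- R[i, j]
      out["SRE"] <- out["SRE"] + v / j^2
      out["LRE"] <- out["LRE"] + v * j^2
      out["LGLRE"] <- out["LGLRE"] + v / i^2
      out["HGLRE"] <- out["HGLRE"] + v * i^2
      out["SRLGLE"] <- out["SRLGLE"] + v / (i^2 * j^2)
      out["SRHGLE"] <- out["SRHGLE"] + v * i^2 / j^2
      out["LRLGLE"] <- out["LRLGLE"] + v * j^2 / i^2
      out["LRHGLE"] <- out["LRHGLE"] + v * i^2 * j^2
    }
  }
  for (j in seq_len(ncol(R))) out["RLN"] <- out["RLN"] + sum(R[, j])^2
  for (nm in setdiff(names(out), "RP")) out[nm] <- out[nm] / Nr
  setNames(out, paste0("glrlm_", names(out)))
}

bruteCCC <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n +
               (mean(x) - mean(y))^2)
}

bruteKruskalP <- function(values, labels) {
  labels <- as.factor(labels)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, labels, function(g) length(g) * (mean(g) - (N + 1) / 2)^2))
  ties <- table(values)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  pchisq(H, df = nlevels(labels) - 1, lower.tail = FALSE)
}

# Quade statistic from its definition (within-block ranks weighted by
# ranks of the block ranges, F distributed)
bruteQuadeP <- function(m) {
  n <- nrow(m); k <- ncol(m)
  Rij <- t(apply(m, 1, rank))
  Q <- rank(apply(m, 1, function(r) max(r) - min(r)))
  S <- Q * (Rij - (k + 1) / 2)
  Sj <- colSums(S)
  A <- sum(S^2)
  B <- sum(Sj^2) / n
  if (A == B) return(pchisq(0, 1))  # degenerate; caller avoids this
  Fstat <- (n - 1) * B / (A - B)
  pf(Fstat, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)
}

# exact multinomial p by enumerating all k^n label assignments
bruteMultinomialP <- function(counts, prob) {
  n <- sum(counts); k <- length(counts)
  prob <- prob / sum(prob)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  outcomeP <- function(cnt) {
    sum(apply(grid, 1, function(assign) {
      if (all(tabulate(assign, nbins = k) == cnt))
        prod(prob[assign]) else 0
    }))
  }
  pObs <- outcomeP(counts)
  total <- 0
  compositions <- function(prefix, remaining, slot) {
    if (slot == k) {
      cnt <- c(prefix, remaining)
      p <- outcomeP(cnt)
      if (p <= pObs * (1 + 1e-10)) total <<- total + p
      return(invisible(NULL))
    }
    for (v in 0:remaining)
      compositions(c(prefix, v), remaining - v, slot + 1L)
  }
  compositions(integer(0), n, 1L)
  total
}

# Wilson bounds by numeric inversion of the binomial score test
bruteWilson <- function(successes, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  g <- function(p0) (phat - p0)^2 - z^2 * p0 * (1 - p0) / n
  # avoid the trivial roots at p0 = phat for the boundary cases
  lower <- if (successes == 0) 0 else
    uniroot(g, c(1e-12, if (successes == n) 1 - 1e-9 else phat),
            tol = 1e-12)$root
  upper <- if (successes == n) 1 else
    uniroot(g, c(if (successes == 0) 1e-9 else phat, 1 - 1e-12),
            tol = 1e-12)$root
  c(lower = lower, upper = upper)
}
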