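# internal helpers shared across modules

# run code under a temporary RNG state derived from `seed`
withSeed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# 8-connected component labelling. EBImage::bwlabel uses 4-connectivity;
# diagonal-touching components are merged afterwards via union-find.
label8 <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(EBImage::imageData(lab))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs only (4-neighbours already share labels)
  for (s in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), , drop = FALSE]
    b <- lab[seq_len(nr - 1L) + 1L, , drop = FALSE]
    if (s[2] == 1L) {
      a <- a[, seq_len(nc - 1L), drop = FALSE]
      b <- b[, seq_len(nc - 1L) + 1L, drop = FALSE]
    } else {
      a <- a[, seq_len(nc - 1L) + 1L, drop = FALSE]
      b <- b[, seq_len(nc - 1L), drop = FALSE]
    }
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) {
      pairs <- unique(cbind(a[keep], b[keep]))
      for (k in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# sizes (pixel counts) of 8-connected components
componentSizes <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L])
}

# morphological skeleton by Zhang-Suen thinning
skeletonize <- function(mask) {
  img <- (mask != 0) * 1L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  shift <- function(m, dr, dc)
    m[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
        (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
        (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        p[cond] <- 0L
        pad[2:(nr + 1L), 2:(nc + 1L)] <- p
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE] > 0L
}

# skeleton pixels with >= 3 skeleton neighbours (8-neighbourhood)
branchPoints <- function(skel) {
  s <- (skel != 0) * 1L
  nb <- neighbourCount(s)
  sum(s == 1L & nb >= 3L)
}

# per-pixel count of foreground 8-neighbours
neighbourCount <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  }
  out
}

# shift a matrix by (dr, dc) pixels, replicating edge values
shiftMatrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian smoothing with replicated borders (sigma in pixels)
gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  convSymRows(convSymRows(t(m), k), k) |> t()
}

# 1-D convolution of each matrix column with kernel k (odd length),
# symmetric (reflect) boundary; applied along rows via transposition
convSymRows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  idxTop <- pmin(pmax(rev(seq_len(r) + 1L), 1L), nr)
  idxBot <- pmin(pmax(nr - seq_len(r), 1L), nr)
  ext <- rbind(m[idxTop, , drop = FALSE], m, m[idxBot, , drop = FALSE])
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * ext[(seq_len(nr)) + (j - 1L), , drop = FALSE]
  out
}

# box-filter local mean with replicated borders (odd window)
localMean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  k <- rep(1 / w, w)
  repRows <- function(x) {
    nr <- nrow(x)
    rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(nr, r), , drop = FALSE])
  }
  colpass <- function(x) {
    ext <- repRows(x)
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_len(w))
      out <- out + k[j] * ext[seq_len(nrow(x)) + (j - 1L), , drop = FALSE]
    out
  }
  t(colpass(t(colpass(m))))
}

# Dice overlap of two binary masks
diceOverlap <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
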