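# 2-D discrete and stationary wavelet transforms.
#
# Implemented from first principles because no wavelet package ships with
# the supported stack. The decimated transform uses periodized filtering
# (input padded symmetrically to a multiple of 2^level, cropped after
# reconstruction), which gives exact perfect reconstruction for the
# biorthogonal filter pairs used here. Filter coefficients are the
# standard published values for the biorthogonal 3.7 and coiflet-1
# wavelets.

.wavelets <- list(
  bior3.7 = list(
    dec_lo = c(0.0030210861012608843, -0.0090632583037826529,
               -0.016831765421310641, 0.074663985074019001,
               0.031332978707362888, -0.301159125922835,
               -0.026499240945345469, 0.95164212189717856,
               0.95164212189717856, -0.026499240945345469,
               -0.301159125922835, 0.031332978707362888,
               0.074663985074019001, -0.016831765421310641,
               -0.0090632583037826529, 0.0030210861012608843),
    dec_hi = c(0, 0, 0, 0, 0, 0,
               -0.17677669529663689, 0.5303300858899106,
               -0.5303300858899106, 0.17677669529663689,
               0, 0, 0, 0, 0, 0),
    rec_lo = c(0, 0, 0, 0, 0, 0,
               0.17677669529663689, 0.5303300858899106,
               0.5303300858899106, 0.17677669529663689,
               0, 0, 0, 0, 0, 0),
    rec_hi = c(0.0030210861012608843, 0.0090632583037826529,
               -0.016831765421310641, -0.074663985074019001,
               0.031332978707362888, 0.301159125922835,
               -0.026499240945345469, -0.95164212189717856,
               0.95164212189717856, 0.026499240945345469,
               -0.301159125922835, -0.031332978707362888,
               0.074663985074019001, 0.016831765421310641,
               -0.0090632583037826529, -0.0030210861012608843)),
  coif1 = list(
    dec_lo = c(-0.015655728135791993, -0.07273261951252645,
               0.38486484686485778, 0.85257202021160039,
               0.33789766245748182, -0.07273261951252645),
    dec_hi = c(0.07273261951252645, 0.33789766245748182,
               -0.85257202021160039, 0.38486484686485778,
               0.07273261951252645, -0.015655728135791993),
    rec_lo = c(-0.07273261951252645, 0.33789766245748182,
               0.85257202021160039, 0.38486484686485778,
               -0.07273261951252645, -0.015655728135791993),
    rec_hi = c(-0.015655728135791993, 0.07273261951252645,
               0.38486484686485778, -0.85257202021160039,
               0.33789766245748182, 0.07273261951252645)))

waveletFilters <- function(name) {
  w <- .wavelets[[name]]
  if (is.null(w)) stop("unsupported wavelet: ", name)
  w
}

# cache of analysis/synthesis operator matrices, keyed by (N, wavelet)
.dwtCache <- new.env(parent = emptyenv())

dwtOperators <- function(N, wavelet) {
  key <- paste0(wavelet, ":", N)
  if (!is.null(.dwtCache[[key]])) return(.dwtCache[[key]])
  w <- waveletFilters(wavelet)
  L <- length(w$dec_lo); K <- N %/% 2L
  Alo <- matrix(0, K, N); Ahi <- matrix(0, K, N)
  for (k in 0:(K - 1L)) {
    idx <- ((2L * k + 1L - (0:(L - 1L))) %% N) + 1L
    for (m in seq_len(L)) {
      Alo[k + 1L, idx[m]] <- Alo[k + 1L, idx[m]] + w$dec_lo[m]
      Ahi[k + 1L, idx[m]] <- Ahi[k + 1L, idx[m]] + w$dec_hi[m]
    }
  }
  off <- L - 2L
  Slo <- matrix(0, N, K); Shi <- matrix(0, N, K)
  for (k in 0:(K - 1L)) {
    idx <- ((2L * k + (0:(L - 1L)) - off) %% N) + 1L
    for (m in seq_len(L)) {
      Slo[idx[m], k + 1L] <- Slo[idx[m], k + 1L] + w$rec_lo[m]
      Shi[idx[m], k + 1L] <- Shi[idx[m], k + 1L] + w$rec_hi[m]
    }
  }
  ops <- list(Alo = Alo, Ahi = Ahi, Slo = Slo, Shi = Shi)
  .dwtCache[[key]] <- ops
  ops
}

# single-level 2-D periodized DWT of an even-sized matrix
dwt2Level <- function(x, wavelet) {
  opr <- dwtOperators(nrow(x), wavelet)
  opc <- dwtOperators(ncol(x), wavelet)
  lo <- opr$Alo %*% x; hi <- opr$Ahi %*% x
  list(LL = lo %*% t(opc$Alo), LH = lo %*% t(opc$Ahi),
       HL = hi %*% t(opc$Alo), HH = hi %*% t(opc$Ahi))
}

idwt2Level <- function(cf, wavelet) {
  opr <- dwtOperators(2L * nrow(cf$LL), wavelet)
  opc <- dwtOperators(2L * ncol(cf$LL), wavelet)
  lo <- cf$LL %*% t(opc$Slo) + cf$LH %*% t(opc$Shi)
  hi <- cf$HL %*% t(opc$Slo) + cf$HH %*% t(opc$Shi)
  opr$Slo %*% lo + opr$Shi %*% hi
}

# symmetric padding of a matrix to target dimensions
padSym <- function(x, nr, nc) {
  padAxis <- function(n, target) {
    if (n >= target) return(seq_len(target))
    extra <- target - n
    c(seq_len(n), rev(seq_len(n))[seq_len(min(extra, n))],
      rep(n, max(0L, extra - n)))
  }
  x[padAxis(nrow(x), nr), padAxis(ncol(x), nc), drop = FALSE]
}

#' Multi-level 2-D discrete wavelet decomposition
#'
#' Periodized separable 2-D DWT. Inputs whose sides are not a multiple
#' of `2^level` are symmetrically padded first; [idwt2()] crops back to
#' the original size. With untouched coefficients,
#' `idwt2(dwt2(x, ...))` reproduces `x` to machine precision.
#'
#' @param x numeric matrix.
#' @param wavelet `"bior3.7"` or `"coif1"`.
#' @param level number of decomposition levels.
#' @return a list with the final approximation `LL` and per-level detail
#'   subbands `details[[l]] = list(LH, HL, HH)`, plus the original
#'   dimensions.
#' @export
dwt2 <- function(x, wavelet = "bior3.7", level = 3L) {
  dims <- dim(x)
  mult <- 2L^level
  target <- ceiling(dims / mult) * mult
  minside <- 2L^level
  if (any(target < minside))
    stop("image too small for a level-", level, " decomposition")
  xp <- padSym(x, target[1], target[2])
  details <- vector("list", level)
  cur <- xp
  for (l in seq_len(level)) {
    cf <- dwt2Level(cur, wavelet)
    details[[l]] <- cf[c("LH", "HL", "HH")]
    cur <- cf$LL
  }
  list(LL = cur, details = details, origDim = dims, wavelet = wavelet,
       level = level)
}

#' @rdname dwt2
#' @param decomp a decomposition produced by [dwt2()].
#' @export
idwt2 <- function(decomp) {
  cur <- decomp$LL
  for (l in rev(seq_len(decomp$level))) {
    cf <- decomp$details[[l]]
    cur <- idwt2Level(list(LL = cur, LH = cf$LH, HL = cf$HL, HH = cf$HH),
                      decomp$wavelet)
  }
  cur[seq_len(decomp$origDim[1]), seq_len(decomp$origDim[2]), drop = FALSE]
}

#' Level-1 stationary (undecimated) 2-D wavelet transform
#'
#' Shift-invariant single-level decomposition: each subband has the same
#' size as the input. Used for the wavelet-based feature class with the
#' coiflet-1 wavelet. Boundaries are handled by symmetric reflection.
#'
#' @param x numeric matrix.
#' @param wavelet wavelet name (default `"coif1"`).
#' @return list of subbands `A` (approximation), `H`, `V`, `D`
#'   (horizontal, vertical, diagonal details), all `dim(x)`.
#' @export
swt2 <- function(x, wavelet = "coif1") {
  w <- waveletFilters(wavelet)
  # centre the filters so kernel length is odd (append zero if needed)
  mk <- function(h) if (length(h) %% 2L == 0L) c(h, 0) else h
  lo <- mk(w$dec_lo); hi <- mk(w$dec_hi)
  rowsLo <- convSymRows(x, lo); rowsHi <- convSymRows(x, hi)
  list(A = t(convSymRows(t(rowsLo), lo)),
       H = t(convSymRows(t(rowsLo), hi)),
       V = t(convSymRows(t(rowsHi), lo)),
       D = t(convSymRows(t(rowsHi), hi)))
}
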