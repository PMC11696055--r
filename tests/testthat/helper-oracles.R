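# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (EBImage morphology, vectorised
# quantiles, matrix algebra) so they can act as cross-checks.

# one 8-neighbour dilation by explicit set expansion
brute_dilate_once <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (m[i, j] == 1L) {
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- 1L
      }
    }
  }
  out
}

brute_dilate <- function(m, n) {
  for (i in seq_len(n)) m <- brute_dilate_once(m)
  m
}

# border detection by explicit sort: flag everything <= the interpolated
# percentile of the sorted pixel population
brute_border <- function(gray, pct) {
  v <- sort(as.vector(gray))
  n <- length(v)
  h <- (n - 1) * pct / 100
  lo <- floor(h) + 1
  thr <- v[lo] + (h - floor(h)) * (v[min(lo + 1, n)] - v[lo])
  (gray <= thr) * 1L
}

# longhand one-way ANOVA ICC on an n x k table
longhand_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- sum(x[i, ]) / k
    ssb <- ssb + k * (mi - grand)^2
    for (j in seq_len(k)) ssw <- ssw + (x[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

mask_centroid <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  colMeans(idx)
}

# a small flat-field image with a dark surround, for io/masking tests
flat_fundus <- function(h = 64, w = 64, col = c(150, 90, 60), surround = 8) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(col[ch], h, w)
    plane[1:surround, ] <- 0
    px[, , ch] <- plane
  }
  fundus_image(px)
}
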