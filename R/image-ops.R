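# Low-level image numerics: separable Gaussian filtering implemented as dense
# banded operator matrices (images here are at most a few hundred pixels per
# side, so an n x n operator is cheap and keeps border handling explicit),
# interpolation, CLAHE and histogram equalization.

# 1D Gaussian smoothing operator (n x n). Rows are truncated at the borders
# and renormalized, i.e. "renormalized nearest" boundary handling.
gauss_op <- function(n, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  d <- outer(i, i, "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > radius] <- 0
  K / rowSums(K)
}

# 1D Gaussian first-derivative operator, normalized so a unit ramp maps to 1.
# Border rows are inaccurate (truncated support); callers mask borders.
gauss_deriv_op <- function(n, sigma, radius = ceiling(3 * sigma)) {
  i <- seq_len(n)
  d <- outer(i, i, "-") # d = i - j, response at i from sample j
  g <- exp(-d^2 / (2 * sigma^2))
  g[abs(d) > radius] <- 0
  k <- -ceiling(3 * sigma):ceiling(3 * sigma)
  gk <- exp(-k^2 / (2 * sigma^2))
  norm <- sum(k^2 * gk)
  # out[i] = sum_j D[i,j] f[j], kernel d[k] = k * g(k) / norm with k = i - j
  # response to f(j) = j is sum_k d[k] (i - k) = -sum k^2 g(k)/norm * (-1) = 1
  K <- (-d * g) / norm
  # zero-sum rows over the local support only: no response to constants
  # anywhere (including truncated border rows) without losing locality
  supp <- abs(d) <= radius
  K - (rowSums(K) / rowSums(supp)) * supp
}

# Separable Gaussian blur of a matrix (sigma in pixels, same both axes).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Sr <- gauss_op(nrow(m), sigma)
  Sc <- gauss_op(ncol(m), sigma)
  Sr %*% m %*% t(Sc)
}

# Gaussian-derivative gradients: list(gx, gy); x = columns, y = rows.
gauss_gradient <- function(m, sigma) {
  Sr <- gauss_op(nrow(m), sigma)
  Sc <- gauss_op(ncol(m), sigma)
  Dr <- gauss_deriv_op(nrow(m), sigma)
  Dc <- gauss_deriv_op(ncol(m), sigma)
  list(gx = Sr %*% m %*% t(Dc), gy = Dr %*% m %*% t(Sc))
}

# Bilinear sampling of matrix m at fractional (row, col) positions.
# Out-of-range positions are clamped to the border.
interp_bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# Catmull-Rom cubic interpolation (separable), used for image warping where
# bilinear smoothing would bias subpixel displacement estimates.
interp_cubic <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(pmax(floor(row), 2L), nr - 2L)
  c0 <- pmin(pmax(floor(col), 2L), nc - 2L)
  fr <- row - r0; fc <- col - c0
  wcr <- function(f) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    cbind(
      ((-f + 2) * f - 1) * f / 2,
      (((3 * f - 5) * f) * f + 2) / 2,
      ((-3 * f + 4) * f + 1) * f / 2,
      ((f - 1) * f * f) / 2
    )
  }
  wr <- wcr(fr); wc <- wcr(fc)
  out <- numeric(length(row))
  for (a in 0:3) {
    rowsum_a <- numeric(length(row))
    ra <- pmin(pmax(r0 + a - 1L, 1L), nr)
    for (b in 0:3) {
      cb <- pmin(pmax(c0 + b - 1L, 1L), nc)
      rowsum_a <- rowsum_a + wc[, b + 1L] * m[cbind(ra, cb)]
    }
    out <- out + wr[, a + 1L] * rowsum_a
  }
  out
}

# Linear stretch of intensities to [0, 1]; constant images map to 0.
stretch_full_range <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-based histogram equalization with clipping and bilinear blending of
#' the per-tile intensity mappings, followed by a linear stretch to the full
#' range. Mirrors the preprocessing used ahead of PIV (tile 64 px).
#'
#' @param m numeric image matrix.
#' @param tile tile size in pixels (default 64).
#' @param nbins number of histogram bins (default 256).
#' @param clip clip limit as a multiple of the mean bin count (default 3,
#'   the "maximum slope" of the ImageJ tool).
#' @return equalized image matrix scaled to `[0, 1]`.
#' @export
clahe <- function(m, tile = 64, nbins = 256, clip = 3) {
  nr <- nrow(m); nc <- ncol(m)
  m0 <- stretch_full_range(m)
  bin <- pmin(floor(m0 * nbins) + 1L, nbins)
  ntr <- max(1L, round(nr / tile)); ntc <- max(1L, round(nc / tile))
  redges <- round(seq(0, nr, length.out = ntr + 1))
  cedges <- round(seq(0, nc, length.out = ntc + 1))
  tr <- findInterval(seq_len(nr), redges[-1] + 0.5) + 1L
  tc <- findInterval(seq_len(nc), cedges[-1] + 0.5) + 1L
  # per-tile clipped-cdf mapping: maps bin index -> [0,1]
  maps <- array(0, c(ntr, ntc, nbins))
  centers_r <- (redges[-1] + redges[-(ntr + 1)] + 1) / 2
  centers_c <- (cedges[-1] + cedges[-(ntc + 1)] + 1) / 2
  for (i in seq_len(ntr)) {
    for (j in seq_len(ntc)) {
      sub <- bin[(redges[i] + 1):redges[i + 1], (cedges[j] + 1):cedges[j + 1]]
      h <- tabulate(sub, nbins)
      lim <- clip * mean(h)
      excess <- sum(pmax(h - lim, 0))
      h <- pmin(h, lim) + excess / nbins
      cdf <- cumsum(h) / sum(h)
      maps[i, j, ] <- cdf
    }
  }
  # bilinear blend of the four surrounding tile mappings
  ri <- findInterval(seq_len(nr), centers_r)
  ci <- findInterval(seq_len(nc), centers_c)
  r0 <- pmin(pmax(ri, 1L), ntr); r1 <- pmin(r0 + 1L, ntr)
  c0 <- pmin(pmax(ci, 1L), ntc); c1 <- pmin(c0 + 1L, ntc)
  fr <- if (ntr > 1) {
    span <- centers_r[r1] - centers_r[r0]
    ifelse(span > 0, (seq_len(nr) - centers_r[r0]) / pmax(span, 1e-12), 0)
  } else rep(0, nr)
  fr <- pmin(pmax(fr, 0), 1)
  fc <- if (ntc > 1) {
    span <- centers_c[c1] - centers_c[c0]
    ifelse(span > 0, (seq_len(nc) - centers_c[c0]) / pmax(span, 1e-12), 0)
  } else rep(0, nc)
  fc <- pmin(pmax(fc, 0), 1)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    b <- bin[, j]
    m00 <- maps[cbind(r0, c0[j], b)]; m10 <- maps[cbind(r1, c0[j], b)]
    m01 <- maps[cbind(r0, c1[j], b)]; m11 <- maps[cbind(r1, c1[j], b)]
    out[, j] <- (1 - fr) * ((1 - fc[j]) * m00 + fc[j] * m01) +
      fr * ((1 - fc[j]) * m10 + fc[j] * m11)
  }
  stretch_full_range(out)
}

#' Rank-based histogram equalization with a contrast power
#'
#' Maps intensities to their normalized ranks in `[0, 1]` and raises the
#' result to `power` (power 1 is plain equalization; 1.5 further darkens the
#' low end, enhancing streak contrast in LIC renderings).
#'
#' @param m numeric image matrix.
#' @param power exponent applied to the equalized values (default 1).
#' @return equalized matrix in `[0, 1]`.
#' @export
hist_equalize <- function(m, power = 1) {
  r <- (rank(m, ties.method = "average") - 0.5) / length(m)
  matrix(r^power, nrow(m), ncol(m))
}
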