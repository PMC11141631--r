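# Nematic order statistics: the 2D orientation-order parameter S, local order
# maps and spatial disorder, the spatial autocorrelation C(d) of an axial
# angle lattice, and the x-intercept correlation length.

#' Global 2D orientation-order parameter
#'
#' `S = | < 2 cos^2(theta - theta_bar) - 1 > |` where `theta_bar` is the
#' doubled-angle circular mean of all unmasked vectors (an arithmetic mean of
#' axial angles is ill-defined at the +/-90 wrap). With this reference S
#' equals the doubled-angle resultant length: 0 for isotropy, 1 for perfect
#' alignment, invariant under global rotation and under theta -> theta + 180.
#'
#' @param field an [orientation_field], or a numeric vector of axial angles
#'   in degrees.
#' @return scalar S in `[0, 1]`.
#' @export
global_order <- function(field) {
  ang <- if (inherits(field, "orientation_field")) field_angles(field)
  else as.numeric(field)
  if (length(ang) < 2) stop("need at least 2 unmasked vectors")
  am <- axial_mean(ang)
  abs(mean(2 * cos(deg2rad(ang - am$mean))^2 - 1))
}

#' Local orientation-order map over sliding windows
#'
#' S computed for `window` x `window` grids of vectors at each center
#' position (stride one grid point, windows fully inside the lattice), each
#' window referenced to its own doubled-angle mean. Windows with fewer than
#' two unmasked vectors are `NA`.
#'
#' @param field an [orientation_field] at least `window` x `window`.
#' @param window window side in grid points (default 4).
#' @return object of class `order_map`: list with matrix `local_S`
#'   (`(nr-window+1)` x `(nc-window+1)`), `window`, `S_global`, `grid_size`,
#'   `pixel_size`.
#' @export
local_order_map <- function(field, window = 4) {
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  if (nr < window || nc < window)
    stop("field smaller than the local window")
  c2 <- cos(deg2rad(2 * field$theta)); s2 <- sin(deg2rad(2 * field$theta))
  c2[!field$mask] <- 0; s2[!field$mask] <- 0
  m <- field$mask * 1
  or <- nr - window + 1L; oc <- nc - window + 1L
  sc <- ss <- sn <- matrix(0, or, oc)
  for (i in seq_len(window)) {
    for (j in seq_len(window)) {
      sc <- sc + c2[i:(i + or - 1L), j:(j + oc - 1L)]
      ss <- ss + s2[i:(i + or - 1L), j:(j + oc - 1L)]
      sn <- sn + m[i:(i + or - 1L), j:(j + oc - 1L)]
    }
  }
  local_S <- sqrt(sc^2 + ss^2) / sn
  local_S[sn < 2] <- NA_real_
  structure(list(local_S = local_S, window = window,
                 S_global = if (sum(field$mask) >= 2) global_order(field) else NA_real_,
                 grid_size = field$grid_size, pixel_size = field$pixel_size),
            class = "order_map")
}

#' @export
print.order_map <- function(x, ...) {
  cat(sprintf("order_map: %d x %d windows (%dx%d vectors), S_global = %.3f\n",
              nrow(x$local_S), ncol(x$local_S), x$window, x$window, x$S_global))
  invisible(x)
}

#' Spatial disorder: percent of local windows below an order threshold
#'
#' @param order_map an `order_map` from [local_order_map()].
#' @param threshold order-parameter threshold (default 0.5).
#' @return percentage in `[0, 100]` of (non-`NA`) windows with
#'   `local_S < threshold`.
#' @export
spatial_disorder <- function(order_map, threshold = 0.5) {
  s <- order_map$local_S
  s <- s[!is.na(s)]
  if (length(s) == 0) stop("order map has no valid windows")
  100 * mean(s < threshold)
}

#' Scale a local order map to 8-bit grayscale
#'
#' Local S in `[0, 1]` mapped linearly to integer gray values 0-255, the
#' form used for order heatmap images.
#'
#' @param order_map an `order_map`.
#' @return integer matrix in `[0, 255]` (`NA` preserved).
#' @export
order_map_gray <- function(order_map) {
  g <- round(pmin(pmax(order_map$local_S, 0), 1) * 255)
  storage.mode(g) <- "integer"
  g
}

#' Spatial autocorrelation of an axial angle lattice
#'
#' `C(d) = 2 < cos^2(theta(r) - theta(r + d)) > - 1`, averaged over all
#' unmasked pairs of grid points with the same separation distance `d`.
#' Masked vectors are excluded pairwise. `C(0) = 1` identically. Computed by
#' direct lag enumeration on small lattices and by zero-padded FFT on large
#' ones (identical sums up to floating-point order).
#'
#' Distance classes: by default (`binning = "exact"`) pairs are grouped by
#' their exact Euclidean separation (classes keyed on the integer
#' `dy^2 + dx^2`, so grouping is exact); on a square lattice the d = 1 class
#' then contains exactly the 4-neighbour pairs. `binning = "grid"` instead
#' rounds separations to the nearest multiple of the grid spacing, merging
#' e.g. the sqrt(2) diagonals into the d = 1 class.
#'
#' @param field an [orientation_field] with >= 2 unmasked vectors.
#' @param binning `"exact"` (default) or `"grid"`; see Details.
#' @return object of class `correlation_curve`: data.frame with `d_grid`
#'   (grid units), `d_px`, `d_um`, `C`, `n_pairs` (unordered pair count);
#'   attributes `grid_size`, `pixel_size`.
#' @export
nematic_autocorrelation <- function(field, binning = c("exact", "grid")) {
  binning <- match.arg(binning)
  if (sum(field$mask) < 2) stop("need at least 2 unmasked vectors")
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  c2 <- cos(deg2rad(2 * field$theta)); s2 <- sin(deg2rad(2 * field$theta))
  c2[!field$mask] <- 0; s2[!field$mask] <- 0
  m <- field$mask * 1
  if (nr * nc <= 1200) {
    lag <- lag_sums_direct(c2, s2, m)
  } else {
    lag <- lag_sums_fft(c2, s2, m)
  }
  d2 <- lag$dy^2 + lag$dx^2
  key <- if (binning == "exact") d2 else round(sqrt(d2))
  num <- tapply(lag$num * lag$w, key, sum)
  cnt <- tapply(lag$cnt * lag$w, key, sum)
  keep <- cnt > 0
  kk <- as.numeric(names(num))[keep]
  dgrid <- if (binning == "exact") sqrt(kk) else kk
  C <- as.numeric(num[keep] / cnt[keep])
  n_pairs <- as.numeric(ifelse(dgrid == 0, cnt[keep], cnt[keep] / 2))
  o <- order(dgrid)
  dgrid <- dgrid[o]
  df <- data.frame(d_grid = dgrid,
                   d_px = dgrid * field$grid_size,
                   d_um = dgrid * field$grid_size * field$pixel_size,
                   C = C[o], n_pairs = n_pairs[o])
  df$C[df$d_grid == 0] <- 1 # identity: cos^2(0) pairs
  structure(df, grid_size = field$grid_size, pixel_size = field$pixel_size,
            class = c("correlation_curve", "data.frame"))
}

# Lag sums over the half-plane of displacements (dy > 0, any dx) plus
# (dy = 0, dx >= 0); weight w doubles every lag but (0,0) so that the
# class sums equal full ordered-pair enumeration.
lag_sums_direct <- function(c2, s2, m) {
  nr <- nrow(m); nc <- ncol(m)
  dys <- 0:(nr - 1)
  res_dy <- integer(0); res_dx <- integer(0)
  res_num <- numeric(0); res_cnt <- numeric(0)
  for (dy in dys) {
    dxs <- if (dy == 0) 0:(nc - 1) else (-(nc - 1)):(nc - 1)
    for (dx in dxs) {
      r1 <- 1:(nr - dy); r2 <- (1 + dy):nr
      if (dx >= 0) { c1 <- 1:(nc - dx); cB <- (1 + dx):nc }
      else { c1 <- (1 - dx):nc; cB <- 1:(nc + dx) }
      a_c <- c2[r1, c1, drop = FALSE]; b_c <- c2[r2, cB, drop = FALSE]
      a_s <- s2[r1, c1, drop = FALSE]; b_s <- s2[r2, cB, drop = FALSE]
      a_m <- m[r1, c1, drop = FALSE]; b_m <- m[r2, cB, drop = FALSE]
      res_dy <- c(res_dy, dy); res_dx <- c(res_dx, dx)
      res_num <- c(res_num, sum(a_c * b_c + a_s * b_s))
      res_cnt <- c(res_cnt, sum(a_m * b_m))
    }
  }
  w <- ifelse(res_dy == 0 & res_dx == 0, 1, 2)
  list(dy = res_dy, dx = res_dx, num = res_num, cnt = res_cnt, w = w)
}

lag_sums_fft <- function(c2, s2, m) {
  nr <- nrow(m); nc <- ncol(m)
  P <- stats::nextn(2 * nr - 1, 2); Q <- stats::nextn(2 * nc - 1, 2)
  pad <- function(x) { p <- matrix(0, P, Q); p[1:nr, 1:nc] <- x; p }
  acorr <- function(x) {
    F <- stats::fft(pad(x))
    Re(stats::fft(F * Conj(F), inverse = TRUE)) / (P * Q)
  }
  ac <- acorr(c2) + acorr(s2)
  am <- acorr(m)
  dy <- 0:(nr - 1)
  dxs <- (-(nc - 1)):(nc - 1)
  grid <- expand.grid(dy = dy, dx = dxs)
  grid <- grid[grid$dy > 0 | grid$dx >= 0, ]
  # autocorrelation at lag (dy, dx): a[(dy mod P)+1, (dx mod Q)+1],
  # where a[k] = sum_r f(r) f(r + k)
  ii <- (grid$dy %% P) + 1L
  jj <- (grid$dx %% Q) + 1L
  idx <- cbind(ii, jj)
  w <- ifelse(grid$dy == 0 & grid$dx == 0, 1, 2)
  list(dy = grid$dy, dx = grid$dx, num = ac[idx], cnt = am[idx], w = w)
}

#' Correlation length as the x-intercept of a short linear fit
#'
#' Ordinary least squares on the first `n_fit` points of the autocorrelation
#' curve; the correlation length is the x-intercept `-intercept/slope`,
#' converted to micrometres with the pixel size. A non-negative slope, or an
#' intercept beyond the maximum sampled distance, is degenerate: the length
#' is clamped to the maximum sampled distance and flagged.
#'
#' @param curve a `correlation_curve` with at least 2 distance classes
#'   (normally >= `n_fit`).
#' @param n_fit number of leading points in the fit (default 10).
#' @return list: `xi_um`, `xi_px`, `xi_grid`, `slope`, `intercept` (per-px
#'   fit), `n_fit` (points used), `degenerate` flag.
#' @export
correlation_length <- function(curve, n_fit = 10) {
  if (nrow(curve) < 2) stop("need at least 2 distance classes")
  if (nrow(curve) < n_fit)
    warning("curve has fewer classes than n_fit; using all of them")
  n_use <- min(n_fit, nrow(curve))
  d <- curve$d_px[seq_len(n_use)]
  C <- curve$C[seq_len(n_use)]
  fit <- stats::lm.fit(cbind(1, d), C)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  dmax <- max(curve$d_px)
  degenerate <- FALSE
  if (!is.finite(b) || b >= 0) {
    xi_px <- dmax; degenerate <- TRUE
  } else {
    xi_px <- -a / b
    if (xi_px > dmax || xi_px <= 0) { xi_px <- dmax; degenerate <- TRUE }
  }
  px <- attr(curve, "pixel_size")
  gs <- attr(curve, "grid_size")
  list(xi_um = unname(xi_px * px), xi_px = unname(xi_px),
       xi_grid = unname(xi_px / gs), slope = unname(b), intercept = unname(a),
       n_fit = n_use, degenerate = degenerate)
}
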