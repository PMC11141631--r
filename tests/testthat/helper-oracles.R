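# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals they check.

# O(N^2) spatial autocorrelation: double loop over all unordered pairs of
# unmasked grid points, grouped by distance class.
brute_autocorr <- function(field, binning = "exact") {
  th <- field$theta; m <- field$mask
  pts <- which(m, arr.ind = TRUE)
  n <- nrow(pts)
  vals <- list(); cnts <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      dy <- pts[j, 1] - pts[i, 1]; dx <- pts[j, 2] - pts[i, 2]
      d2 <- dy^2 + dx^2
      key <- if (binning == "exact") sprintf("%d", d2)
      else sprintf("%d", round(sqrt(d2)))
      v <- cos(2 * pi / 180 * (th[pts[i, 1], pts[i, 2]] - th[pts[j, 1], pts[j, 2]]))
      vals[[key]] <- sum(vals[[key]], v)
      cnts[[key]] <- sum(cnts[[key]], 1)
    }
  }
  keys <- names(vals)
  d <- if (binning == "exact") sqrt(as.numeric(keys)) else as.numeric(keys)
  o <- order(d)
  data.frame(d_grid = d[o],
             C = unlist(vals)[o] / unlist(cnts)[o])
}

# Literal per-window order parameter: mean angle via doubled-angle mean,
# then S = |<2 cos^2(theta - mean) - 1>|.
brute_window_S <- function(angles) {
  t2 <- 2 * angles * pi / 180
  mbar <- atan2(mean(sin(t2)), mean(cos(t2))) / 2
  abs(mean(2 * cos(angles * pi / 180 - mbar)^2 - 1))
}

# Dense-pair correlation-length oracle: regress per-pair cos(2 dtheta) on
# exact pair distance over d <= dmax (px), x-intercept in px.
dense_xi_oracle <- function(field, dmax_px) {
  th <- field$theta; m <- field$mask
  pts <- which(m, arr.ind = TRUE)
  gs <- field$grid_size
  dy <- outer(pts[, 1], pts[, 1], "-"); dx <- outer(pts[, 2], pts[, 2], "-")
  d <- sqrt(dy^2 + dx^2) * gs
  ang <- th[pts]
  cv <- cos(2 * pi / 180 * outer(ang, ang, "-"))
  sel <- upper.tri(d, diag = TRUE) & d <= dmax_px
  fit <- stats::lm.fit(cbind(1, d[sel]), cv[sel])
  unname(-fit$coefficients[1] / fit$coefficients[2])
}

# sinusoidal stripe image whose stripes run along `angle` degrees
stripe_image <- function(n, angle, wavelength = 12) {
  a <- angle * pi / 180
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  0.5 + 0.5 * cos(2 * pi / wavelength * (-x * sin(a) + y * cos(a)))
}

# random points with a minimum pairwise separation (rejection sampling)
separated_points <- function(n, lo, hi, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 50000) {
    p <- stats::runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) > min_sep) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1
  }
  stopifnot(nrow(pts) == n)
  pts
}

# fraction of ground-truth steps recovered by a linked track set: a truth
# step is recovered if some linked step has both endpoints within tol um.
step_recovery <- function(truth, linked, tol = 2) {
  step_table <- function(ts) {
    do.call(rbind, lapply(split(as.data.frame(ts), ts$track_id), function(d) {
      if (nrow(d) < 2) return(NULL)
      data.frame(f0 = d$frame[-nrow(d)], x0 = d$x_um[-nrow(d)],
                 y0 = d$y_um[-nrow(d)], x1 = d$x_um[-1], y1 = d$y_um[-1])
    }))
  }
  st <- step_table(truth); sl <- step_table(linked)
  hit <- 0
  for (f in unique(st$f0)) {
    a <- st[st$f0 == f, ]; b <- sl[sl$f0 == f, , drop = FALSE]
    if (is.null(b) || nrow(b) == 0) next
    for (i in seq_len(nrow(a))) {
      d0 <- sqrt((b$x0 - a$x0[i])^2 + (b$y0 - a$y0[i])^2)
      d1 <- sqrt((b$x1 - a$x1[i])^2 + (b$y1 - a$y1[i])^2)
      if (any(d0 < tol & d1 < tol)) hit <- hit + 1
    }
  }
  hit / nrow(st)
}

# noise-free, non-crossing movie fixture: contact-avoiding random walkers
# with a border margin, rendered as Gaussian nuclear spots
noncrossing_movie <- function(n_cells = 40, n_frames = 15, n_px = 256,
                              step_sd = 3, min_sep = 28, margin = 20,
                              spot_sigma = 12 / 2.355, seed = 1) {
  set.seed(seed)
  pos <- separated_points(n_cells, margin, n_px - margin, min_sep)
  rows <- list()
  frames <- list()
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      for (i in seq_len(n_cells)) {
        for (try in 1:20) {
          cand <- pos[i, ] + stats::rnorm(2, 0, step_sd)
          cand <- pmin(pmax(cand, margin), n_px - margin)
          d <- sqrt((pos[-i, 1] - cand[1])^2 + (pos[-i, 2] - cand[2])^2)
          if (min(d) > min_sep) { pos[i, ] <- cand; break }
        }
      }
    }
    rows[[f]] <- data.frame(track_id = seq_len(n_cells), frame = f,
                            t_h = f - 1, x_um = pos[, 1], y_um = pos[, 2])
    frames[[f]] <- cellnematics:::render_spots(n_px, pos[, 1], pos[, 2],
                                               spot_sigma)
  }
  list(tracks = track_set(do.call(rbind, rows), frame_interval = 1,
                          field_area_mm2 = (n_px / 1000)^2),
       frames = frames)
}
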