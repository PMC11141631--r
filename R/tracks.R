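# Nuclei detection (scale-normalized LoG blobs with a physical diameter
# gate), greedy mutual-nearest-neighbour track linking, cell density and
# aligned time, and migration statistics (speed, direction, directional bias,
# division axis).

#' Cell track table
#'
#' A data.frame of per-cell trajectories with columns `track_id`, `frame`,
#' `t_h` (hours), `x_um`, `y_um`, carrying the frame interval and imaged
#' field area as attributes. Frames must be strictly increasing within each
#' track.
#'
#' @param df data.frame with the columns above.
#' @param frame_interval hours between frames.
#' @param field_area_mm2 imaged area in mm^2.
#' @return object of class `track_set` (a data.frame).
#' @export
track_set <- function(df, frame_interval, field_area_mm2) {
  need <- c("track_id", "frame", "t_h", "x_um", "y_um")
  stopifnot(all(need %in% names(df)), frame_interval > 0, field_area_mm2 > 0)
  df <- df[order(df$track_id, df$frame), need]
  bad <- tapply(df$frame, df$track_id, function(f) any(diff(f) <= 0))
  if (any(unlist(bad))) stop("frames must be strictly increasing within a track")
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            field_area_mm2 = field_area_mm2,
            class = c("track_set", "data.frame"))
}

#' Detect nuclei as scale-normalized LoG blobs with a diameter gate
#'
#' Multi-scale Laplacian-of-Gaussian detection of bright spots, with
#' 3x3(x3-scale) local-maximum selection and quadratic subpixel refinement.
#' The detected scale is converted to a Gaussian-FWHM equivalent diameter
#' (`2.355 * sigma * pixel_size` um) and detections outside
#' `diameter_range` are excluded (the 6-30 um nuclear size gate). The scale
#' sweep extends 40% beyond the gate on both sides so oversized/undersized
#' blobs are detected at their true scale and then rejected, rather than
#' being clipped into range.
#'
#' @param image numeric matrix, intensities roughly in `[0, 1]`.
#' @param pixel_size micrometres per pixel.
#' @param diameter_range length-2 gate in micrometres (default `c(6, 30)`).
#' @param threshold minimum scale-normalized LoG response (default 0.1;
#'   a unit-amplitude Gaussian spot responds ~0.5).
#' @param n_scales number of log-spaced scales (default 9).
#' @return data.frame: `x_px`, `y_px`, `x_um`, `y_um`, `sigma_px`,
#'   `diameter_um`, `response`.
#' @export
detect_nuclei <- function(image, pixel_size = 1, diameter_range = c(6, 30),
                          threshold = 0.1, n_scales = 9) {
  stopifnot(is.matrix(image), pixel_size > 0, diameter_range[1] > 0,
            diameter_range[2] > diameter_range[1])
  nr <- nrow(image); nc <- ncol(image)
  sig_lo <- diameter_range[1] / 2.355 / pixel_size / 1.4
  sig_hi <- diameter_range[2] / 2.355 / pixel_size * 1.4
  sigmas <- exp(seq(log(sig_lo), log(sig_hi), length.out = n_scales))
  resp <- array(0, c(nr, nc, n_scales))
  for (k in seq_len(n_scales)) {
    resp[, , k] <- -sigmas[k]^2 * log_filter(image, sigmas[k])
  }
  hits <- NULL
  for (k in seq_len(n_scales)) {
    r <- resp[, , k]
    mx <- spatial_local_maxima(r)
    if (k > 1) mx <- mx & r >= resp[, , k - 1]
    if (k < n_scales) mx <- mx & r >= resp[, , k + 1]
    mx <- mx & r >= threshold
    idx <- which(mx)
    if (length(idx) == 0) next
    yy <- (idx - 1) %% nr + 1
    xx <- (idx - 1) %/% nr + 1
    hits <- rbind(hits, data.frame(y = yy, x = xx, k = k, resp = r[idx]))
  }
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(x_px = numeric(), y_px = numeric(), x_um = numeric(),
                      y_um = numeric(), sigma_px = numeric(),
                      diameter_um = numeric(), response = numeric()))
  # greedy non-maximum suppression across scales: strongest first,
  # suppress anything within its sigma
  hits <- hits[order(-hits$resp), ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- hits[keep, , drop = FALSE]
    dmin <- min(sqrt((prev$x - hits$x[i])^2 + (prev$y - hits$y[i])^2))
    keep[i] <- dmin > sigmas[hits$k[i]]
  }
  hits <- hits[keep, , drop = FALSE]
  # subpixel refinement by 1D quadratic fits at the detected scale
  refine <- function(y, x, k) {
    r <- resp[, , k]
    dy <- dx <- 0
    if (y > 1 && y < nr) {
      den <- r[y - 1, x] - 2 * r[y, x] + r[y + 1, x]
      if (den < 0) dy <- 0.5 * (r[y - 1, x] - r[y + 1, x]) / den
    }
    if (x > 1 && x < nc) {
      den <- r[y, x - 1] - 2 * r[y, x] + r[y, x + 1]
      if (den < 0) dx <- 0.5 * (r[y, x - 1] - r[y, x + 1]) / den
    }
    c(y + max(min(dy, 0.5), -0.5), x + max(min(dx, 0.5), -0.5))
  }
  pos <- t(mapply(refine, hits$y, hits$x, hits$k))
  out <- data.frame(x_px = pos[, 2], y_px = pos[, 1],
                    x_um = pos[, 2] * pixel_size, y_um = pos[, 1] * pixel_size,
                    sigma_px = sigmas[hits$k],
                    diameter_um = 2.355 * sigmas[hits$k] * pixel_size,
                    response = hits$resp)
  out <- out[out$diameter_um >= diameter_range[1] &
               out$diameter_um <= diameter_range[2], ]
  rownames(out) <- NULL
  out
}

# Laplacian of Gaussian via separable Gaussian second-derivative operators.
log_filter <- function(m, sigma) {
  Sr <- gauss_op(nrow(m), sigma); Sc <- gauss_op(ncol(m), sigma)
  D2r <- gauss_d2_op(nrow(m), sigma); D2c <- gauss_d2_op(ncol(m), sigma)
  D2r %*% (m %*% t(Sc)) + (Sr %*% m) %*% t(D2c)
}

# 1D Gaussian second-derivative operator; rows sum to zero (no DC response)
# and the response to x^2/2 is 1.
gauss_d2_op <- function(n, sigma, radius = ceiling(4 * sigma)) {
  i <- seq_len(n)
  d <- outer(i, i, "-")
  g <- exp(-d^2 / (2 * sigma^2))
  g[abs(d) > radius] <- 0
  k <- -ceiling(4 * sigma):ceiling(4 * sigma)
  gk <- exp(-k^2 / (2 * sigma^2))
  d2k <- (k^2 / sigma^4 - 1 / sigma^2) * gk
  norm <- sum(k^2 * d2k) / 2 # response of x^2/2
  K <- (d^2 / sigma^4 - 1 / sigma^2) * g / norm
  supp <- abs(d) <= radius
  K - (rowSums(K) / rowSums(supp)) * supp # zero DC over the local support
}

# strict-or-equal 8-neighbour spatial local maxima (ties allowed)
spatial_local_maxima <- function(r) {
  nr <- nrow(r); nc <- ncol(r)
  mx <- matrix(TRUE, nr, nc)
  shift <- function(m, dy, dx) {
    out <- matrix(-Inf, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    mx <- mx & r >= shift(r, dy, dx)
  }
  mx[c(1, nr), ] <- FALSE
  mx[, c(1, nc)] <- FALSE
  mx
}

#' Link detections into tracks by greedy mutual nearest neighbours
#'
#' Frame-to-frame linking: a detection in frame f is linked to one in frame
#' f+1 iff each is the other's nearest neighbour and their distance is at
#' most `max_disp`. Unmatched detections start new tracks; there is no gap
#' closing. Ties are resolved by smallest distance, then lowest index.
#'
#' @param detections list (one element per frame) of data.frames with
#'   columns `x_um`, `y_um`.
#' @param max_disp maximum link distance in micrometres per frame.
#' @param frame_interval hours between frames.
#' @param field_area_mm2 imaged area in mm^2.
#' @return a [track_set].
#' @export
link_tracks <- function(detections, max_disp, frame_interval = 1,
                        field_area_mm2 = 1) {
  stopifnot(length(detections) >= 1)
  nextid <- 1L
  cur <- detections[[1]]
  cur_id <- if (nrow(cur) > 0) seq_len(nrow(cur)) else integer()
  nextid <- nrow(cur) + 1L
  rows <- list()
  add_rows <- function(f, det, ids) {
    if (nrow(det) == 0) return(NULL)
    data.frame(track_id = ids, frame = f, t_h = (f - 1) * frame_interval,
               x_um = det$x_um, y_um = det$y_um)
  }
  rows[[1]] <- add_rows(1L, cur, cur_id)
  for (f in seq_along(detections)[-1]) {
    nxt <- detections[[f]]
    nxt_id <- integer(nrow(nxt))
    if (nrow(cur) > 0 && nrow(nxt) > 0) {
      D <- outer(cur$x_um, nxt$x_um, "-")^2 + outer(cur$y_um, nxt$y_um, "-")^2
      D <- sqrt(D)
      nn_fwd <- apply(D, 1, which.min)
      nn_bwd <- apply(D, 2, which.min)
      for (i in seq_len(nrow(cur))) {
        j <- nn_fwd[i]
        if (nn_bwd[j] == i && D[i, j] <= max_disp) nxt_id[j] <- cur_id[i]
      }
    }
    new <- which(nxt_id == 0L)
    if (length(new) > 0) {
      nxt_id[new] <- seq.int(nextid, length.out = length(new))
      nextid <- nextid + length(new)
    }
    rows[[f]] <- add_rows(f, nxt, nxt_id)
    cur <- nxt; cur_id <- nxt_id
  }
  track_set(do.call(rbind, rows), frame_interval = frame_interval,
            field_area_mm2 = field_area_mm2)
}

#' Cell density per frame
#'
#' Detection (or track-point) counts divided by the imaged area.
#'
#' @param x a [track_set], or a list of per-frame data.frames.
#' @param field_area_mm2 area in mm^2 (taken from the track_set if missing).
#' @param frame_interval hours between frames (likewise).
#' @return data.frame: `frame`, `t_h`, `n`, `density` (cells/mm^2).
#' @export
cell_density <- function(x, field_area_mm2 = NULL, frame_interval = NULL) {
  if (inherits(x, "track_set")) {
    if (is.null(field_area_mm2)) field_area_mm2 <- attr(x, "field_area_mm2")
    if (is.null(frame_interval)) frame_interval <- attr(x, "frame_interval")
    counts <- table(factor(x$frame, levels = seq_len(max(x$frame))))
  } else {
    stopifnot(!is.null(field_area_mm2), field_area_mm2 > 0)
    if (is.null(frame_interval)) frame_interval <- 1
    counts <- vapply(x, nrow, numeric(1))
  }
  n <- as.numeric(counts)
  data.frame(frame = seq_along(n), t_h = (seq_along(n) - 1) * frame_interval,
             n = n, density = n / field_area_mm2)
}

#' Align a density time series so its peak sits at a target time
#'
#' The density is smoothed with a centered moving average (window 3) and the
#' time axis shifted so the smoothed maximum falls at `target_peak` hours
#' (peak density at t_a ~ 36 h corresponds to confluence at t_a ~ 0 h). The
#' returned offset is meant to be applied to all companion series (order,
#' disorder, speed, velocity correlation length) of the same movie. A series
#' still rising at its last point, or a flat series, is flagged with a
#' message (offset still computed; 0 for flat).
#'
#' @param density data.frame with `t_h` and `density` (from [cell_density()]).
#' @param target_peak hours (default 36).
#' @return the input with columns `t_a` and `density_smooth` added;
#'   attributes `offset_h` and `flagged`.
#' @export
align_time_series <- function(density, target_peak = 36) {
  stopifnot(nrow(density) >= 3, all(c("t_h", "density") %in% names(density)))
  d <- density$density
  sm <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(d[1:2]); sm[length(d)] <- mean(d[(length(d) - 1):length(d)])
  sm <- as.numeric(sm)
  flagged <- FALSE
  if (max(sm) - min(sm) <= 1e-12 * max(abs(sm), 1)) {
    message("flat density series: offset set to 0")
    offset <- 0; flagged <- TRUE
    peak <- length(sm)
  } else {
    peak <- which.max(sm)
    if (peak == length(sm)) {
      message("density still rising at the last time point; peak = last point")
      flagged <- TRUE
    }
    offset <- target_peak - density$t_h[peak]
  }
  out <- density
  out$density_smooth <- sm
  out$t_a <- density$t_h + offset
  structure(out, offset_h = offset, flagged = flagged)
}

#' Per-step and per-cell migration statistics
#'
#' Step displacements between consecutive track points give speeds
#' (um/hour) and directions (`atan2(dy, dx)` degrees in `(-180, 180]`).
#' Zero-length steps contribute speed 0 and no angle (`NA`). Per-cell means
#' use the vector mean of unit step directions.
#'
#' @param ts a [track_set].
#' @return list: `steps` (track_id, frame, t_h, speed_umh, angle_deg),
#'   `cells` (track_id, n_steps, mean_speed_umh, mean_angle_deg).
#' @export
migration_stats <- function(ts) {
  sp <- split(as.data.frame(ts), ts$track_id)
  steps <- lapply(sp, function(d) {
    if (nrow(d) < 2) return(NULL)
    dt <- diff(d$t_h); dx <- diff(d$x_um); dy <- diff(d$y_um)
    disp <- sqrt(dx^2 + dy^2)
    data.frame(track_id = d$track_id[-1], frame = d$frame[-1],
               t_h = d$t_h[-1], speed_umh = disp / dt,
               angle_deg = ifelse(disp == 0, NA_real_,
                                  wrap_direction(rad2deg(atan2(dy, dx)))))
  })
  steps <- do.call(rbind, steps[!vapply(steps, is.null, logical(1))])
  if (is.null(steps))
    stop("no track has two or more points")
  rownames(steps) <- NULL
  cells <- do.call(rbind, lapply(split(steps, steps$track_id), function(d) {
    ok <- !is.na(d$angle_deg)
    ma <- if (any(ok)) {
      wrap_direction(rad2deg(atan2(mean(sin(deg2rad(d$angle_deg[ok]))),
                                   mean(cos(deg2rad(d$angle_deg[ok]))))))
    } else NA_real_
    data.frame(track_id = d$track_id[1], n_steps = nrow(d),
               mean_speed_umh = mean(d$speed_umh), mean_angle_deg = ma)
  }))
  rownames(cells) <- NULL
  list(steps = steps, cells = cells)
}

#' Normalized directional migration along the director
#'
#' Step directions are histogrammed into `360 / bin_width` bins (18 bins of
#' 20 degrees by default) and the summed frequency of the two bins flanking
#' the director is divided by the isotropic expectation for 2 bins out of 18
#' (2/18 = 11.111%). A ratio of 1 means no directional preference; 9 means
#' every step falls in the flanking bins.
#'
#' @param angles step directions in degrees, `(-180, 180]` (`NA` dropped).
#' @param director reference direction in degrees (default 0).
#' @param bin_width bin width in degrees; must divide 360 (default 20).
#' @return list: `ratio`, `numerator` (summed frequency of the two flanking
#'   bins), `denominator` (isotropic expectation `2 / n_bins`), `n` steps.
#' @export
normalized_directional_migration <- function(angles, director = 0,
                                             bin_width = 20) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0)
    return(list(ratio = NA_real_, numerator = NA_real_,
                denominator = 2 / (360 / bin_width), n = 0L))
  rel <- wrap_direction(angles - director)
  edges <- seq(-180, 180, by = bin_width)
  idx <- findInterval(rel, edges, left.open = TRUE)
  idx[idx == 0L] <- 1L
  nb <- length(edges) - 1L
  freq <- tabulate(idx, nb) / length(rel)
  zlo <- which(edges[-length(edges)] < 0 & edges[-1] >= 0) # bin (-bw, 0]
  numerator <- freq[zlo] + freq[zlo + 1L]
  denominator <- 2 / nb
  list(ratio = numerator / denominator, numerator = numerator,
       denominator = denominator, n = length(rel))
}

#' Per-time-point normalized directional migration series
#'
#' @param steps step table from [migration_stats()].
#' @param director,bin_width as in [normalized_directional_migration()].
#' @return data.frame: `frame`, `t_h`, `ratio`, `n` (`NA` ratio where a time
#'   point has no steps with direction).
#' @export
normalized_migration_series <- function(steps, director = 0, bin_width = 20) {
  out <- do.call(rbind, lapply(split(steps, steps$frame), function(d) {
    r <- normalized_directional_migration(d$angle_deg, director, bin_width)
    data.frame(frame = d$frame[1], t_h = d$t_h[1], ratio = r$ratio, n = r$n)
  }))
  rownames(out) <- NULL
  out
}

#' Average per-replicate profiles on a common density lattice
#'
#' Linear interpolation of each replicate's (density, value) relation onto a
#' lattice with the given increment (10 cells/mm^2), then the pointwise mean
#' across replicates (equal weight per replicate; lattice points covered by
#' fewer than `min_n` replicates are dropped).
#'
#' @param replicates list of data.frames with columns `density` and `value`.
#' @param increment lattice spacing in cells/mm^2 (default 10).
#' @param min_n minimum replicates per lattice point (default 1).
#' @return data.frame: `density`, `mean_value`, `n`.
#' @export
density_profile_average <- function(replicates, increment = 10, min_n = 1) {
  stopifnot(length(replicates) >= 1)
  lo <- min(vapply(replicates, function(d) min(d$density), numeric(1)))
  hi <- max(vapply(replicates, function(d) max(d$density), numeric(1)))
  lattice <- seq(ceiling(lo / increment) * increment, hi, by = increment)
  vals <- vapply(replicates, function(d) {
    o <- order(d$density)
    stats::approx(d$density[o], d$value[o], xout = lattice, ties = mean)$y
  }, numeric(length(lattice)))
  vals <- matrix(vals, nrow = length(lattice))
  n <- rowSums(!is.na(vals))
  keep <- n >= min_n
  data.frame(density = lattice[keep],
             mean_value = rowMeans(vals, na.rm = TRUE)[keep],
             n = n[keep])
}

#' Division-axis frequency distribution
#'
#' The axis angle between paired daughter nuclei, measured from the
#' horizontal (the nematic director), folded to the nematic range
#' `(-90, 90]` and binned in 20-degree increments.
#'
#' @param pairs data.frame with columns `x1`, `y1`, `x2`, `y2`.
#' @param bin_width degrees, must divide 180 (default 20).
#' @return a `frequency_distribution` over `(-90, 90]`.
#' @export
division_axis <- function(pairs, bin_width = 20) {
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(pairs)))
  dx <- pairs$x2 - pairs$x1; dy <- pairs$y2 - pairs$y1
  if (any(dx == 0 & dy == 0)) stop("coincident nucleus pairs are not allowed")
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  ang <- wrap_nematic(rad2deg(atan2(dy, dx)))
  edges <- seq(-90, 90, by = bin_width)
  idx <- findInterval(ang, edges, left.open = TRUE)
  idx[idx == 0L] <- 1L
  counts <- tabulate(idx, length(edges) - 1L)
  frequency_distribution(edges, counts / sum(counts))
}
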