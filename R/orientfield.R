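# Orientation-field extraction: structure-tensor pixel maps, coherency-gated
# grid sampling, angular frequency distributions, peak normalization, and a
# thin threshold/label/ellipse routine for single-cell shape metrics.

#' Structure-tensor local orientation of an image
#'
#' Gaussian-derivative gradients are formed at scale `sigma_gradient`; the
#' tensor products gx^2, gy^2, gx*gy are smoothed with a Gaussian window of
#' scale `sigma_window` (the "sigma" of the analysis, 10 or 20 px for
#' myotube-scale texture). The orientation is that of the eigenvector of the
#' smaller eigenvalue — the structure direction, perpendicular to the dominant
#' gradient: `theta = 0.5 * atan2(-2 Jxy, Jyy - Jxx)`. Coherency is the
#' eigenvalue contrast `(l1 - l2) / (l1 + l2)` in `[0, 1]`, set to 0 where
#' the tensor energy vanishes; theta is `NA` (masked) there.
#'
#' @param image 2D numeric matrix (grayscale).
#' @param sigma_window tensor smoothing window in pixels (> 0).
#' @param sigma_gradient gradient scale in pixels (> 0, default 1).
#' @return object of class `pixel_orientation_map`: list with matrices
#'   `theta` (degrees, nematic range, `NA` where masked), `coherency`,
#'   `energy`, and the scalar `sigma` (= `sigma_window`).
#' @export
structure_tensor <- function(image, sigma_window, sigma_gradient = 1) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2D numeric matrix")
  stopifnot(sigma_window > 0, sigma_gradient > 0)
  g <- gauss_gradient(image, sigma_gradient)
  Jxx <- gauss_blur(g$gx * g$gx, sigma_window)
  Jyy <- gauss_blur(g$gy * g$gy, sigma_window)
  Jxy <- gauss_blur(g$gx * g$gy, sigma_window)
  energy <- Jxx + Jyy
  theta <- wrap_nematic(rad2deg(atan2(-2 * Jxy, Jyy - Jxx)) / 2)
  contrast <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  # absolute floor tied to the intensity scale: flat regions produce only
  # floating-point dust whose contrast/energy ratio is meaningless
  tol <- 1e-12 * max(energy) + (1e-9 * (max(abs(image)) + 1e-12))^2
  flat <- energy <= tol
  coherency <- ifelse(flat, 0, contrast / pmax(energy, tol))
  theta[flat] <- NA_real_
  structure(list(theta = theta, coherency = pmin(pmax(coherency, 0), 1),
                 energy = energy, sigma = sigma_window,
                 sigma_gradient = sigma_gradient),
            class = "pixel_orientation_map")
}

#' @export
print.pixel_orientation_map <- function(x, ...) {
  cat(sprintf("pixel_orientation_map: %d x %d px, sigma %.3g px, %d masked\n",
              nrow(x$theta), ncol(x$theta), x$sigma, sum(is.na(x$theta))))
  invisible(x)
}

#' Sample a pixel orientation map onto a regular grid
#'
#' One vector per complete `grid_size` x `grid_size` cell: the angle is the
#' coherency-weighted doubled-angle mean of the cell's pixels, and the cell is
#' masked where the mean coherency falls below `min_coherency` (the 25%
#' coherency gate of the vector-field analysis) or no pixel carries weight.
#'
#' @param pmap a `pixel_orientation_map`.
#' @param grid_size cell size in pixels (>= 1; must not exceed the image).
#' @param min_coherency mask cells with mean coherency below this (default 0.25).
#' @param pixel_size micrometres per pixel recorded on the output (default 1).
#' @return an [orientation_field] on the cell-center lattice.
#' @export
sample_grid <- function(pmap, grid_size, min_coherency = 0.25, pixel_size = 1) {
  nr <- nrow(pmap$theta); nc <- ncol(pmap$theta)
  grid_size <- as.integer(grid_size)
  if (grid_size < 1) stop("grid_size must be >= 1")
  if (grid_size > nr || grid_size > nc)
    stop("grid_size exceeds the image extent")
  gr <- nr %/% grid_size; gc <- nc %/% grid_size
  c2 <- cos(deg2rad(2 * pmap$theta)); s2 <- sin(deg2rad(2 * pmap$theta))
  w <- pmap$coherency
  w[is.na(pmap$theta)] <- 0
  c2[is.na(c2)] <- 0; s2[is.na(s2)] <- 0
  # block sums via row/col aggregation
  block <- function(m) {
    m <- m[seq_len(gr * grid_size), seq_len(gc * grid_size), drop = FALSE]
    rowgrp <- rep(seq_len(gr), each = grid_size)
    colgrp <- rep(seq_len(gc), each = grid_size)
    t(rowsum(t(rowsum(m, rowgrp)), colgrp))
  }
  sw <- block(w)
  swc <- block(w * c2); sws <- block(w * s2)
  scoh <- block(pmap$coherency)
  npix <- grid_size^2
  theta <- wrap_nematic(rad2deg(atan2(sws, swc)) / 2)
  mean_coh <- scoh / npix
  mask <- sw > 0 & mean_coh >= min_coherency
  theta[!mask] <- NA_real_
  orientation_field(theta, coherency = pmin(pmax(mean_coh, 0), 1),
                    mask = mask, grid_size = grid_size,
                    pixel_size = pixel_size,
                    origin = c((grid_size + 1) / 2, (grid_size + 1) / 2))
}

#' Angular frequency distribution of orientations
#'
#' Coherency-gated angles histogrammed over the nematic range `(-90, 90]`
#' and normalized to frequencies (sum 1). For pixel maps, border pixels
#' within `2 * sigma` of the image edge are excluded (incomplete gradient
#' support); for fields, masked vectors are excluded.
#'
#' @param x a `pixel_orientation_map` or an [orientation_field].
#' @param bin_width bin width in degrees; must divide 180 (default 20, the
#'   binning used for alignment frequency plots).
#' @param min_coherency exclude angles below this coherency (default 0).
#' @return object of class `frequency_distribution`: data.frame with
#'   `bin_lo`, `bin_hi`, `bin_mid` (degrees) and `frequency`; attribute
#'   `bin_width`.
#' @export
orientation_histogram <- function(x, bin_width = 20, min_coherency = 0) {
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  if (inherits(x, "pixel_orientation_map")) {
    keep <- !is.na(x$theta) & x$coherency >= min_coherency
    b <- ceiling(2 * x$sigma)
    nr <- nrow(x$theta); nc <- ncol(x$theta)
    if (2 * b < nr - 1 && 2 * b < nc - 1) {
      inner <- matrix(FALSE, nr, nc)
      inner[(b + 1):(nr - b), (b + 1):(nc - b)] <- TRUE
      keep <- keep & inner
    }
    ang <- x$theta[keep]
  } else if (inherits(x, "orientation_field")) {
    keep <- x$mask & x$coherency >= min_coherency
    ang <- x$theta[keep]
  } else stop("x must be a pixel_orientation_map or orientation_field")
  if (length(ang) == 0) stop("no angles remain after coherency gating")
  edges <- seq(-90, 90, by = bin_width)
  # (-90, 90] with right-closed bins
  idx <- findInterval(ang, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L # exactly -90 cannot occur after wrapping; guard anyway
  counts <- tabulate(idx, length(edges) - 1L)
  frequency_distribution(edges, counts / sum(counts))
}

frequency_distribution <- function(edges, freq) {
  df <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                   bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                   frequency = freq)
  structure(df, bin_width = diff(edges)[1], class = c("frequency_distribution",
                                                      "data.frame"))
}

#' Shift two angular distributions so a reference peaks at zero
#'
#' Both distributions are circularly shifted (by whole bins) by the mode
#' angle of `reference`, so the reference mode lands on the bin containing
#' zero. Used to re-reference ECM orientation to the myotube alignment peak;
#' the shifted axis is "Normalized Angle (deg)". A multimodal tie picks the
#' lowest-angle mode and messages.
#'
#' @param dist `frequency_distribution` to shift.
#' @param reference `frequency_distribution` supplying the mode (same binning).
#' @return shifted `frequency_distribution` with attributes `shift_deg` and
#'   `axis_label = "Normalized Angle (deg)"`.
#' @export
normalize_to_peak <- function(dist, reference) {
  bw <- attr(dist, "bin_width")
  if (!identical(bw, attr(reference, "bin_width")) ||
      !isTRUE(all.equal(dist$bin_lo, reference$bin_lo)))
    stop("dist and reference must share the same binning")
  mx <- which(reference$frequency == max(reference$frequency))
  if (length(mx) > 1L) {
    message("multimodal reference: choosing the lowest-angle mode")
    mx <- mx[1L]
  }
  shift_bins <- mx - which(dist$bin_lo < 0 & dist$bin_hi >= 0)
  n <- nrow(dist)
  idx <- ((seq_len(n) - 1 + shift_bins) %% n) + 1
  out <- dist
  out$frequency <- dist$frequency[idx]
  attr(out, "shift_deg") <- reference$bin_mid[mx]
  attr(out, "axis_label") <- "Normalized Angle (deg)"
  out
}

#' Threshold, label and fit ellipses to cells in an image
#'
#' Otsu threshold, 4-connected component labeling, and a second-moment
#' ellipse per component: area, centroid, major/minor axis, aspect ratio and
#' orientation (nematic degrees). Components touching fewer than `min_px`
#' pixels are dropped.
#'
#' @param image numeric matrix.
#' @param pixel_size micrometres per pixel (default 1); areas are reported in
#'   um^2 and axes in um.
#' @param min_px minimum component size in pixels (default 9).
#' @return data.frame: `label`, `area_um2`, `x_um`, `y_um`, `major_um`,
#'   `minor_um`, `aspect_ratio`, `orientation_deg`.
#' @export
segment_cells <- function(image, pixel_size = 1, min_px = 9) {
  fg <- image > otsu_threshold(image)
  lab <- label_components(fg)
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      aspect_ratio = numeric(), orientation_deg = numeric()))
  idx <- which(lab > 0)
  l <- lab[idx]
  yy <- (idx - 1) %% nrow(image) + 1
  xx <- (idx - 1) %/% nrow(image) + 1
  res <- lapply(split(seq_along(l), l), function(k) {
    if (length(k) < min_px) return(NULL)
    x <- xx[k]; y <- yy[k]
    mx <- mean(x); my <- mean(y)
    # second central moments with the 1/12 pixel-variance term
    uxx <- mean((x - mx)^2) + 1 / 12
    uyy <- mean((y - my)^2) + 1 / 12
    uxy <- mean((x - mx) * (y - my))
    common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
    major <- 2 * sqrt(2 * (uxx + uyy + common))
    minor <- 2 * sqrt(2 * pmax(uxx + uyy - common, 0))
    ang <- wrap_nematic(rad2deg(atan2(2 * uxy, uxx - uyy)) / 2)
    data.frame(area_um2 = length(k) * pixel_size^2,
               x_um = mx * pixel_size, y_um = my * pixel_size,
               major_um = major * pixel_size, minor_um = minor * pixel_size,
               aspect_ratio = major / max(minor, .Machine$double.eps),
               orientation_deg = ang)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(segment_cells(matrix(0, 2, 2))) # empty frame, same columns
  out <- do.call(rbind, res)
  out <- cbind(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Otsu's threshold on a 256-bin histogram of the stretched image.
otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[1])
  v <- (image - rng[1]) / diff(rng)
  h <- tabulate(pmin(floor(v * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  rng[1] + (k / 256) * diff(rng)
}

# 4-connected component labeling by repeated label propagation (images here
# are small; simplicity over speed).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    old <- lab
    m <- lab
    up <- rbind(m[-1, , drop = FALSE], rep(0L, nc))
    dn <- rbind(rep(0L, nc), m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], rep(0L, nr))
    rt <- cbind(rep(0L, nr), m[, -nc, drop = FALSE])
    for (nb in list(up, dn, lf, rt)) {
      take <- fg & nb > 0 & (lab == 0L | nb < lab)
      lab[take] <- nb[take]
    }
    if (identical(lab, old)) break
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}
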