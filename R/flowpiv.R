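# Multipass windowed-cross-correlation PIV: CLAHE preprocessing, per-window
# normalized FFT cross-correlation with 3-point Gaussian subpixel peak fit,
# coarse-to-fine predictor chaining, and per-frame flow statistics (mean
# speed, velocity correlation length).

#' PIV image preprocessing
#'
#' Contrast-limited adaptive histogram equalization (tile 64 px) followed by
#' a linear stretch to the full intensity range, as applied ahead of the
#' cross-correlation passes.
#'
#' @param image numeric matrix.
#' @param tile CLAHE tile size in pixels (default 64).
#' @return preprocessed image in `[0, 1]`.
#' @export
piv_preprocess <- function(image, tile = 64) {
  stretch_full_range(clahe(image, tile = tile))
}

#' Velocity field on an interrogation lattice
#'
#' Container for one PIV pass/frame: displacement components `u`, `v` in
#' pixels per frame (matrices over the interrogation lattice), lattice pixel
#' coordinates `x`, `y`, a `valid` flag matrix, and the window/step settings.
#' When `frame_interval` (hours) and `pixel_size` (um/px) are supplied,
#' `u_umh`, `v_umh` and `magnitude_umh` give the calibrated velocities.
#'
#' @param u,v displacement matrices in px/frame.
#' @param x,y numeric vectors of lattice center coordinates in pixels.
#' @param valid logical matrix.
#' @param window,step interrogation window and step in pixels.
#' @param frame_interval hours between frames (NA if uncalibrated).
#' @param pixel_size micrometres per pixel (NA if uncalibrated).
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(u, v, x, y, valid, window, step,
                           frame_interval = NA_real_, pixel_size = NA_real_) {
  stopifnot(all(dim(u) == dim(v)), all(dim(u) == dim(valid)),
            length(y) == nrow(u), length(x) == ncol(u))
  obj <- list(u = u, v = v, x = x, y = y, valid = valid,
              window = window, step = step,
              frame_interval = frame_interval, pixel_size = pixel_size)
  if (is.finite(frame_interval) && is.finite(pixel_size)) {
    s <- pixel_size / frame_interval
    obj$u_umh <- u * s; obj$v_umh <- v * s
    obj$magnitude_umh <- sqrt(obj$u_umh^2 + obj$v_umh^2)
  }
  structure(obj, class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "velocity_field: %d x %d vectors (window %d, step %d), %d/%d valid\n",
    nrow(x$u), ncol(x$u), x$window, x$step, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Single PIV pass by normalized FFT cross-correlation
#'
#' For each interrogation window the second image is counter-shifted by the
#' rounded predictor, both windows are zero-mean normalized, the
#' cross-correlation is computed by zero-padded FFT, the peak located within
#' a search radius, and a 3-point Gaussian fit per axis gives the subpixel
#' residual; the total displacement is predictor + residual. Windows whose
#' correlation peak ratio (highest peak over second peak outside its 3x3
#' neighbourhood) is below `min_peak_ratio` are flagged invalid. A light
#' 3x3 median smoothing is applied to the vector lattice (the "lowest
#' setting" vector smoothing).
#'
#' @param imgA,imgB numeric matrices (consecutive frames).
#' @param window interrogation window in pixels (>= 16, <= image size).
#' @param step lattice step in pixels (<= window).
#' @param predictor optional list with matrices `u`, `v` on this pass's
#'   lattice (px/frame), e.g. interpolated from a coarser pass.
#' @param min_peak_ratio validity threshold on the peak ratio (default 1.2).
#' @param smooth apply the 3x3 median vector smoothing (default TRUE).
#' @return a [velocity_field] in px/frame (uncalibrated).
#' @export
piv_pass <- function(imgA, imgB, window, step, predictor = NULL,
                     min_peak_ratio = 1.2, smooth = TRUE) {
  stopifnot(is.matrix(imgA), is.matrix(imgB), all(dim(imgA) == dim(imgB)))
  if (window < 16) stop("window must be >= 16 px")
  if (step > window) stop("step must be <= window")
  nr <- nrow(imgA); nc <- ncol(imgA)
  if (window > nr || window > nc) stop("window larger than image")
  r_lt <- seq(1, nr - window + 1, by = step)
  c_lt <- seq(1, nc - window + 1, by = step)
  y <- r_lt + (window - 1) / 2
  x <- c_lt + (window - 1) / 2
  gy <- length(r_lt); gx <- length(c_lt)
  u <- v <- matrix(0, gy, gx)
  valid <- matrix(TRUE, gy, gx)
  search <- floor(window / 3)
  P <- 2L * as.integer(window)
  lag_of <- function(idx) ifelse(idx - 1 > P / 2, idx - 1 - P, idx - 1)
  for (i in seq_len(gy)) {
    for (j in seq_len(gx)) {
      pu <- 0L; pv <- 0L
      if (!is.null(predictor)) {
        pu <- as.integer(round(predictor$u[i, j]))
        pv <- as.integer(round(predictor$v[i, j]))
      }
      ra <- r_lt[i]:(r_lt[i] + window - 1L)
      ca <- c_lt[j]:(c_lt[j] + window - 1L)
      rb <- ra + pv; cb <- ca + pu
      # keep the counter-shifted window inside the frame
      if (rb[1] < 1) rb <- rb - rb[1] + 1L
      if (rb[window] > nr) rb <- rb - (rb[window] - nr)
      if (cb[1] < 1) cb <- cb - cb[1] + 1L
      if (cb[window] > nc) cb <- cb - (cb[window] - nc)
      pv <- rb[1] - ra[1]; pu <- cb[1] - ca[1]
      a <- imgA[ra, ca]; b <- imgB[rb, cb]
      a <- a - mean(a); b <- b - mean(b)
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) { valid[i, j] <- FALSE; next }
      pa <- matrix(0, P, P); pa[1:window, 1:window] <- a / na
      pb <- matrix(0, P, P); pb[1:window, 1:window] <- b / nb
      cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                          inverse = TRUE)) / (P * P)
      # restrict to the search radius
      sy <- lag_of(row(cc)); sx <- lag_of(col(cc))
      # unbiased normalization: divide by the overlap area of each lag so
      # the correlation taper does not drag the subpixel peak toward zero
      ov <- pmax(window - abs(sy), 1) * pmax(window - abs(sx), 1)
      cc <- cc * (window * window) / ov
      inrange <- abs(sy) <= search & abs(sx) <= search
      ccs <- ifelse(inrange, cc, -Inf)
      pk <- which.max(ccs)
      pky <- sy[pk]; pkx <- sx[pk]
      pkv <- ccs[pk]
      # peak ratio vs second peak outside the 3x3 neighbourhood
      nbhd <- abs(sy - pky) <= 1 & abs(sx - pkx) <= 1
      second <- max(ccs[!nbhd & inrange], -Inf)
      ratio <- if (is.finite(second) && second > 0) pkv / second else Inf
      if (!is.finite(pkv) || ratio < min_peak_ratio) valid[i, j] <- FALSE
      # 3-point Gaussian subpixel fit along each axis
      getcc <- function(dy, dx) {
        ii <- ((pky + dy) %% P) + 1L; jj <- ((pkx + dx) %% P) + 1L
        cc[ii, jj]
      }
      subfit <- function(cm, c0, cp) {
        if (cm > 0 && c0 > 0 && cp > 0) {
          den <- log(cm) - 2 * log(c0) + log(cp)
          if (den < 0) return((log(cm) - log(cp)) / (2 * den))
        }
        den <- cm - 2 * c0 + cp
        if (den < 0) (cm - cp) / (2 * den) else 0
      }
      dy <- subfit(getcc(-1, 0), pkv, getcc(1, 0))
      dx <- subfit(getcc(0, -1), pkv, getcc(0, 1))
      dy <- max(min(dy, 0.5), -0.5); dx <- max(min(dx, 0.5), -0.5)
      u[i, j] <- pu + pkx + dx
      v[i, j] <- pv + pky + dy
    }
  }
  if (smooth) {
    sm <- median_smooth(u, v, valid)
    u <- sm$u; v <- sm$v
  }
  velocity_field(u, v, x, y, valid, window, step)
}

# 3x3 median smoothing of the vector lattice; invalid vectors are replaced
# by the median of their valid neighbours (where any exist).
median_smooth <- function(u, v, valid) {
  gy <- nrow(u); gx <- ncol(u)
  us <- u; vs <- v
  for (i in seq_len(gy)) {
    for (j in seq_len(gx)) {
      ii <- max(1, i - 1):min(gy, i + 1)
      jj <- max(1, j - 1):min(gx, j + 1)
      w <- valid[ii, jj]
      if (!any(w)) next
      us[i, j] <- stats::median(u[ii, jj][w])
      vs[i, j] <- stats::median(v[ii, jj][w])
    }
  }
  list(u = us, v = vs)
}

#' Coarse-to-fine multipass PIV
#'
#' Runs [piv_pass()] for each `(window, step)` setting in order (windows
#' strictly decreasing), bilinearly interpolating each pass's smoothed field
#' onto the next lattice as the predictor. The output lives on the final
#' lattice, calibrated to um/hour, with the outermost vector ring flagged
#' invalid (automated stand-in for manual rejection of boundary artifacts).
#'
#' @param imgA,imgB numeric matrices.
#' @param passes list of `c(window, step)` pairs, coarse to fine, e.g.
#'   `list(c(600, 300), c(300, 150), c(150, 75))`.
#' @param frame_interval hours between the frames.
#' @param pixel_size micrometres per pixel.
#' @param preprocess apply [piv_preprocess()] to both frames first.
#' @param min_peak_ratio passed to [piv_pass()].
#' @return a calibrated [velocity_field].
#' @export
piv_multipass <- function(imgA, imgB, passes, frame_interval = 1,
                          pixel_size = 1, preprocess = FALSE,
                          min_peak_ratio = 1.2) {
  wins <- vapply(passes, `[`, numeric(1), 1)
  steps <- vapply(passes, `[`, numeric(1), 2)
  if (length(wins) > 1 && any(diff(wins) >= 0))
    stop("pass windows must be strictly decreasing")
  if (any(steps > wins)) stop("step must be <= window in every pass")
  if (preprocess) {
    imgA <- piv_preprocess(imgA); imgB <- piv_preprocess(imgB)
  }
  vf <- NULL
  for (p in seq_along(wins)) {
    predictor <- NULL
    if (!is.null(vf)) {
      r_lt <- seq(1, nrow(imgA) - wins[p] + 1, by = steps[p])
      c_lt <- seq(1, ncol(imgA) - wins[p] + 1, by = steps[p])
      yy <- r_lt + (wins[p] - 1) / 2
      xx <- c_lt + (wins[p] - 1) / 2
      # positions in units of the previous lattice
      gr <- (rep(yy, times = length(xx)) - vf$y[1]) / vf$step + 1
      gc <- (rep(xx, each = length(yy)) - vf$x[1]) / vf$step + 1
      predictor <- list(
        u = matrix(interp_bilinear(vf$u, gr, gc), length(yy), length(xx)),
        v = matrix(interp_bilinear(vf$v, gr, gc), length(yy), length(xx)))
    }
    vf <- piv_pass(imgA, imgB, wins[p], steps[p], predictor = predictor,
                   min_peak_ratio = min_peak_ratio)
  }
  valid <- vf$valid
  if (nrow(valid) > 2 && ncol(valid) > 2) {
    valid[c(1, nrow(valid)), ] <- FALSE
    valid[, c(1, ncol(valid))] <- FALSE
  }
  velocity_field(vf$u, vf$v, vf$x, vf$y, valid, vf$window, vf$step,
                 frame_interval = frame_interval, pixel_size = pixel_size)
}

#' Per-frame flow statistics: mean speed and velocity correlation length
#'
#' For each frame in a series of calibrated velocity fields, the mean speed
#' over valid vectors and the velocity correlation length xi_vv. Vector
#' angles are wrapped to the nematic range and passed through the same
#' autocorrelation/x-intercept pipeline as orientation fields (the cos^2 form
#' makes the analysis axial). `mode = "signed"` instead correlates full
#' direction vectors (cos(dphi)); it is provided for comparison but is not
#' the default. Frames listed in `artifact_frames` (e.g. post-medium-change
#' shifts) are dropped from both series; all-invalid frames are dropped with
#' a message.
#'
#' @param fields list of calibrated [velocity_field]s (consistent lattices).
#' @param artifact_frames integer frame indices to drop.
#' @param mode `"nematic"` (default) or `"signed"`.
#' @param n_fit points in the correlation-length fit (default 10).
#' @param binning distance-class mode passed to [nematic_autocorrelation()].
#' @return data.frame: `frame`, `t_h`, `mean_speed_umh`, `xi_vv_um`,
#'   `degenerate`.
#' @export
flow_statistics <- function(fields, artifact_frames = integer(),
                            mode = c("nematic", "signed"), n_fit = 10,
                            binning = "exact") {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(fields), function(f) {
    vf <- fields[[f]]
    if (f %in% artifact_frames) return(NULL)
    if (!any(vf$valid)) {
      message(sprintf("frame %d: no valid vectors, dropped", f))
      return(NULL)
    }
    if (is.null(vf$magnitude_umh))
      stop("velocity fields must be calibrated (frame_interval, pixel_size)")
    spd <- mean(vf$magnitude_umh[vf$valid])
    phi <- rad2deg(atan2(vf$v, vf$u))
    theta <- if (mode == "nematic") wrap_nematic(phi) else phi / 2
    fld <- orientation_field(theta, coherency = 1, mask = vf$valid,
                             grid_size = vf$step, pixel_size = vf$pixel_size,
                             origin = c(vf$x[1], vf$y[1]))
    xi <- if (sum(vf$valid) >= 2) {
      correlation_length(nematic_autocorrelation(fld, binning = binning),
                         n_fit = n_fit)
    } else list(xi_um = NA_real_, degenerate = TRUE)
    data.frame(frame = f, t_h = (f - 1) * vf$frame_interval,
               mean_speed_umh = spd, xi_vv_um = xi$xi_um,
               degenerate = xi$degenerate)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
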