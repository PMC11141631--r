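# Synthetic-data generators. Every generator takes an explicit seed and leaves
# the caller's RNG state untouched, so identical arguments give bit-identical
# output regardless of context.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Uniform director field
#'
#' All grid angles equal `theta0`, coherency 1: the perfect-order limit
#' (downstream order parameter exactly 1).
#'
#' @param shape integer length-2, grid dimensions (rows, cols).
#' @param theta0 director angle in degrees, must lie in `(-90, 90]`.
#' @param grid_size,pixel_size lattice spacing (px) and calibration (um/px).
#' @return an [orientation_field].
#' @export
gen_uniform_field <- function(shape, theta0, grid_size = 1, pixel_size = 1) {
  if (theta0 <= -90 || theta0 > 90)
    stop("theta0 must lie in the nematic range (-90, 90]")
  orientation_field(matrix(theta0, shape[1], shape[2]),
                    coherency = 1, grid_size = grid_size,
                    pixel_size = pixel_size)
}

#' Spatially correlated random director field
#'
#' Samples two independent unit-variance Gaussian noise fields (the components
#' of the doubled-angle vector), smooths each with an isotropic Gaussian
#' kernel of scale `smoothing_scale` grid units, and takes half the argument
#' of the smoothed 2-vector. Valid nematic angles by construction; the
#' correlation length grows monotonically with the smoothing scale (the map is
#' empirical, not analytic).
#'
#' @param shape grid dimensions (rows, cols).
#' @param smoothing_scale Gaussian smoothing scale in grid units (>= 0;
#'   0 gives i.i.d. angles).
#' @param seed integer RNG seed.
#' @param grid_size,pixel_size lattice spacing (px) and calibration (um/px).
#' @return an [orientation_field] with coherency 1 everywhere.
#' @export
gen_correlated_field <- function(shape, smoothing_scale, seed,
                                 grid_size = 1, pixel_size = 1) {
  stopifnot(smoothing_scale >= 0)
  with_seed(seed, {
    a <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    b <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    if (smoothing_scale > 0) {
      a <- gauss_blur(a, smoothing_scale)
      b <- gauss_blur(b, smoothing_scale)
    }
    theta <- rad2deg(atan2(b, a)) / 2
    orientation_field(theta, coherency = 1, grid_size = grid_size,
                      pixel_size = pixel_size)
  })
}

#' Analytic director field with half-integer topological defects
#'
#' Builds `theta(r) = sum_i k_i * atan2(y - y_i, x - x_i) + theta0`, reduced
#' to the nematic range. Half-integer charges are the defects characteristic
#' of nematics; the winding number around any loop equals the sum of enclosed
#' charges.
#'
#' @param shape grid dimensions (rows, cols).
#' @param defect_list data.frame (or matrix) with columns `x`, `y` (grid
#'   coordinates; col/row) and `charge` (+1/2 or -1/2). Empty gives a uniform
#'   field at `theta0`.
#' @param theta0 background angle in degrees.
#' @param grid_size,pixel_size lattice spacing (px) and calibration (um/px).
#' @return an [orientation_field].
#' @export
gen_defect_field <- function(shape, defect_list = NULL, theta0 = 0,
                             grid_size = 1, pixel_size = 1) {
  theta <- matrix(theta0, shape[1], shape[2])
  if (!is.null(defect_list) && NROW(defect_list) > 0) {
    dl <- as.data.frame(defect_list)
    stopifnot(all(c("x", "y", "charge") %in% names(dl)))
    if (!all(abs(dl$charge) == 0.5))
      stop("defect charges must be +1/2 or -1/2")
    if (any(dl$x < 1 | dl$x > shape[2] | dl$y < 1 | dl$y > shape[1]))
      stop("defect cores must lie inside the domain")
    if (anyDuplicated(dl[, c("x", "y")]))
      stop("coincident defect cores are not allowed")
    x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    y <- matrix(seq_len(shape[1]), shape[1], shape[2])
    for (i in seq_len(nrow(dl))) {
      theta <- theta + dl$charge[i] * rad2deg(atan2(y - dl$y[i], x - dl$x[i]))
    }
  }
  orientation_field(theta, coherency = 1, grid_size = grid_size,
                    pixel_size = pixel_size)
}

#' Filament-textured image following a director field
#'
#' Renders short anti-aliased line segments at random positions, each oriented
#' at the local field angle plus Gaussian jitter (sigma 3 degrees, below the
#' structure-tensor tolerance), emulating actin texture whose local
#' orientation follows the field.
#'
#' @param field an [orientation_field]; the image covers its lattice extent.
#' @param filament_length segment length in pixels.
#' @param filament_density segments per pixel of image area.
#' @param seed integer RNG seed.
#' @param jitter_sd orientation jitter sd in degrees (default 3).
#' @return numeric image matrix in `[0, 1]`.
#' @export
gen_filament_image <- function(field, filament_length = 15,
                               filament_density = 0.02, seed = 1,
                               jitter_sd = 3) {
  nr <- round(nrow(field$theta) * field$grid_size)
  nc <- round(ncol(field$theta) * field$grid_size)
  n <- round(filament_density * nr * nc)
  if (n == 0) return(matrix(0, nr, nc))
  with_seed(seed, {
    cx <- stats::runif(n, 1, nc)
    cy <- stats::runif(n, 1, nr)
    # sample the field's doubled-angle components bilinearly at the centers
    gr <- (cy - field$origin[2]) / field$grid_size + 1
    gc <- (cx - field$origin[1]) / field$grid_size + 1
    c2 <- interp_bilinear(cos(deg2rad(2 * field$theta)), gr, gc)
    s2 <- interp_bilinear(sin(deg2rad(2 * field$theta)), gr, gc)
    ang <- rad2deg(atan2(s2, c2)) / 2 + stats::rnorm(n, 0, jitter_sd)
    tpar <- seq(-filament_length / 2, filament_length / 2, by = 0.5)
    px <- rep(cx, each = length(tpar)) +
      tpar * cos(deg2rad(rep(ang, each = length(tpar))))
    py <- rep(cy, each = length(tpar)) +
      tpar * sin(deg2rad(rep(ang, each = length(tpar))))
    keep <- px >= 1 & px <= nc & py >= 1 & py <= nr
    px <- px[keep]; py <- py[keep]
    # bilinear splatting into the accumulator
    c0 <- floor(px); r0 <- floor(py)
    fc <- px - c0; fr <- py - r0
    ii <- c(r0, r0 + 1, r0, r0 + 1)
    jj <- c(c0, c0, c0 + 1, c0 + 1)
    ww <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    acc <- as.matrix(Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = ww[ok],
                                          dims = c(nr, nc)))
    img <- gauss_blur(acc, 0.8)
    pmin(img / stats::quantile(img[img > 0], 0.95), 1)
  })
}

#' Speckle (tracer-like) test image
#'
#' Random small Gaussian spots, the classic PIV texture: its sharp isotropic
#' autocorrelation peak supports subpixel displacement fitting at full
#' precision, unlike elongated filament textures whose broad anisotropic
#' peaks bias 3-point fits.
#'
#' @param n image side in pixels.
#' @param n_spots number of spots (default `0.03 * n^2`).
#' @param spot_sigma spot sd in pixels (default 1.5).
#' @param seed RNG seed.
#' @return numeric image matrix.
#' @export
gen_speckle_image <- function(n, n_spots = round(0.03 * n^2),
                              spot_sigma = 1.5, seed = 1) {
  with_seed(seed, {
    render_spots(n, stats::runif(n_spots, 1, n), stats::runif(n_spots, 1, n),
                 spot_sigma)
  })
}

#' Image pair displaced by a known flow
#'
#' The second image is the first resampled backward along the flow, so image
#' features move forward by the flow between the two frames: a ground-truth
#' fixture for PIV. Constant flows use an exact Fourier phase shift (periodic
#' boundary); spatially varying flows use Catmull-Rom cubic resampling.
#'
#' @param image numeric matrix (frame A).
#' @param flow either a numeric length-2 `(ux, uy)` constant displacement in
#'   pixels, or a list with matrices `u`, `v` of per-pixel displacements.
#' @return list of two image matrices `a`, `b`.
#' @export
gen_displaced_pair <- function(image, flow) {
  if (is.numeric(flow) && length(flow) == 2L) {
    b <- fourier_shift(image, flow[1], flow[2])
  } else {
    stopifnot(is.list(flow), all(dim(flow$u) == dim(image)),
              all(dim(flow$v) == dim(image)))
    nr <- nrow(image); nc <- ncol(image)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - flow$u
    row <- matrix(seq_len(nr), nr, nc) - flow$v
    b <- matrix(interp_cubic(image, as.vector(row), as.vector(col)), nr, nc)
  }
  list(a = image, b = b)
}

# Exact subpixel shift by Fourier phase ramp; features move by (+ux, +uy).
fourier_shift <- function(m, ux, uy) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- 0:(nr - 1); kr[kr > nr / 2] <- kr[kr > nr / 2] - nr
  kc <- 0:(nc - 1); kc[kc > nc / 2] <- kc[kc > nc / 2] - nc
  phase <- exp(-2i * pi * (outer(kr * uy / nr, rep(1, nc)) +
                             outer(rep(1, nr), kc * ux / nc)))
  Re(stats::fft(stats::fft(m) * phase, inverse = TRUE)) / (nr * nc)
}

#' Simulated nuclei movie: biased persistent random walk with logistic growth
#'
#' Cell count follows logistic growth to a carrying capacity; each cell
#' performs a persistent random walk whose step directions are biased toward
#' the 0-degree director with the given strength, and whose speed decays with
#' crowding. Optionally renders per-frame images of Gaussian nuclear spots.
#' Defaults describe a confluent myoblast-like culture: carrying capacity
#' 4000 cells/mm^2, peak density reached within the movie, speeds of order
#' 15 um/hour before crowding.
#'
#' @param n_frames number of frames.
#' @param frame_interval hours between frames.
#' @param field_size_px field of view side length in pixels (square).
#' @param pixel_size micrometres per pixel.
#' @param capacity carrying capacity in cells/mm^2 (default 4000).
#' @param rate logistic growth rate in 1/hour (default 0.05).
#' @param n0_frac initial density as a fraction of capacity (default 0.1).
#' @param speed base speed in um/hour (default 15).
#' @param persistence direction persistence weight in `[0, 1)` (default 0.7).
#' @param bias strength of the directional bias toward 0 degrees (>= 0;
#'   `Inf` makes every step exactly along the director).
#' @param nucleus_diameter_um rendered nuclear spot FWHM in um (default 12).
#' @param render if `TRUE`, return per-frame spot images.
#' @param seed integer RNG seed.
#' @return list with `tracks` (a [track_set]), `density` (data.frame of the
#'   true per-frame density), and `frames` (list of image matrices, or NULL).
#' @export
gen_growth_tracks <- function(n_frames = 40, frame_interval = 1,
                              field_size_px = 200, pixel_size = 1,
                              capacity = 4000, rate = 0.05, n0_frac = 0.1,
                              speed = 15, persistence = 0.7, bias = 0,
                              nucleus_diameter_um = 12, render = TRUE,
                              seed = 1) {
  stopifnot(n_frames >= 2, frame_interval > 0, capacity > 0, rate > 0,
            speed > 0, persistence >= 0, persistence < 1, bias >= 0)
  L_um <- field_size_px * pixel_size
  area_mm2 <- (L_um / 1000)^2
  K <- max(2, round(capacity * area_mm2))
  n0 <- max(2, round(n0_frac * K))
  with_seed(seed, {
    tt <- (seq_len(n_frames) - 1) * frame_interval
    counts <- round(K / (1 + ((K - n0) / n0) * exp(-rate * tt)))
    counts <- pmax(counts, n0)
    x <- y <- phi <- numeric(0)
    alive <- logical(0)
    spawn <- function(idx) {
      x[idx] <<- stats::runif(length(idx), 0, L_um)
      y[idx] <<- stats::runif(length(idx), 0, L_um)
      phi[idx] <<- stats::runif(length(idx), -pi, pi)
      alive[idx] <<- TRUE
    }
    rows <- vector("list", n_frames)
    grow <- function(k) {
      # extend state vectors so k new cells fit
      extra <- rep(NA_real_, k)
      x <<- c(x, extra); y <<- c(y, extra); phi <<- c(phi, extra)
      alive <<- c(alive, rep(FALSE, k))
    }
    for (f in seq_len(n_frames)) {
      ia <- which(alive)
      if (f > 1 && length(ia) > 0) {
        dens <- counts[f] / area_mm2
        v <- speed * max(0.1, 1 - 0.8 * dens / capacity)
        if (is.infinite(bias)) {
          phi[ia] <- 0
        } else {
          wx <- persistence * cos(phi[ia]) + bias +
            stats::rnorm(length(ia), 0, 0.5)
          wy <- persistence * sin(phi[ia]) +
            stats::rnorm(length(ia), 0, 0.5)
          phi[ia] <- atan2(wy, wx)
        }
        x[ia] <- x[ia] + v * frame_interval * cos(phi[ia])
        y[ia] <- y[ia] + v * frame_interval * sin(phi[ia])
        # cells that walk out of the field of view leave the movie;
        # their tracks end and newcomers enter elsewhere
        gone <- ia[x[ia] < 0 | x[ia] > L_um | y[ia] < 0 | y[ia] > L_um]
        alive[gone] <- FALSE
      }
      need <- counts[f] - sum(alive)
      if (need > 0) {
        grow(need)
        idx <- length(alive) - need + seq_len(need)
        spawn(idx)
      }
      ia <- which(alive)
      rows[[f]] <- data.frame(track_id = ia, frame = f, t_h = tt[f],
                              x_um = x[ia], y_um = y[ia])
    }
    tracks <- track_set(do.call(rbind, rows), frame_interval = frame_interval,
                        field_area_mm2 = area_mm2)
    frames <- NULL
    if (render) {
      spot_sigma_px <- nucleus_diameter_um / 2.355 / pixel_size
      frames <- lapply(rows, function(df) {
        render_spots(field_size_px, df$x_um / pixel_size, df$y_um / pixel_size,
                     spot_sigma_px)
      })
    }
    list(tracks = tracks,
         density = data.frame(frame = seq_len(n_frames), t_h = tt,
                              density = counts / area_mm2),
         frames = frames)
  })
}

# Render Gaussian spots (sd sigma px) at pixel positions (x, y) on an n x n
# image; amplitude 1 per spot.
render_spots <- function(n, x, y, sigma) {
  img <- matrix(0, n, n)
  if (length(x) == 0) return(img)
  r <- ceiling(3.5 * sigma)
  for (i in seq_along(x)) {
    c0 <- max(1, floor(x[i]) - r); c1 <- min(n, floor(x[i]) + r + 1)
    r0 <- max(1, floor(y[i]) - r); r1 <- min(n, floor(y[i]) + r + 1)
    if (c1 < c0 || r1 < r0) next
    dx2 <- (c0:c1 - x[i])^2
    dy2 <- (r0:r1 - y[i])^2
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  pmin(img, 1)
}
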