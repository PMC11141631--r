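# Topological defect detection in director fields: winding numbers along
# closed loops, plaquette-charge localization of +/-1/2 cores, and
# line-integral-convolution rendering of the field texture.

#' Winding number of a director field along a closed loop
#'
#' Sums consecutive angle differences along the loop, each mapped to the
#' nematic range `(-90, 90]`, and divides by 360: half-integer values are
#' the nematic defect charges. The result is reported rounded to the nearest
#' half-integer together with the rounding residual.
#'
#' @param field an [orientation_field].
#' @param loop integer matrix with columns `row`, `col`: closed
#'   counter-clockwise loop of grid points (first point not repeated).
#' @return list: `charge` (nearest half-integer), `raw` (unrounded), and
#'   `residual` (`raw - charge`).
#' @export
winding_number <- function(field, loop) {
  loop <- as.matrix(loop)
  stopifnot(ncol(loop) == 2, nrow(loop) >= 3)
  if (any(!field$mask[loop])) stop("loop crosses masked grid points")
  ang <- field$theta[loop]
  d <- wrap_nematic(diff(c(ang, ang[1])))
  raw <- sum(d) / 360
  charge <- round(raw * 2) / 2
  list(charge = charge, raw = raw, residual = raw - charge)
}

# Square counter-clockwise loop of side 2*half centered at (row, col).
square_loop <- function(row, col, half) {
  r0 <- row - half; r1 <- row + half
  c0 <- col - half; c1 <- col + half
  rbind(
    cbind(r0, c0:c1),                 # bottom edge, left -> right
    cbind((r0 + 1):r1, c1),           # right edge, up
    cbind(r1, (c1 - 1):c0),           # top edge, right -> left
    cbind((r1 - 1):(r0 + 1), c0)      # left edge, down
  )
}

# Charge of every unit plaquette: sum of the four nematically wrapped angle
# differences around each elementary cell, in units of full turns. Exactly a
# multiple of 1/2 wherever all four corners are valid; NA otherwise.
plaquette_charges <- function(field) {
  th <- field$theta
  nr <- nrow(th); nc <- ncol(th)
  a <- th[-nr, -nc]; b <- th[-nr, -1]; cc <- th[-1, -1]; d <- th[-1, -nc]
  q <- (wrap_nematic(b - a) + wrap_nematic(cc - b) +
          wrap_nematic(d - cc) + wrap_nematic(a - d)) / 360
  m <- field$mask
  ok <- m[-nr, -nc] & m[-nr, -1] & m[-1, -1] & m[-1, -nc]
  q[!ok] <- NA_real_
  q
}

#' Detect half-integer topological defects
#'
#' The winding number is evaluated on square loops of side `tensorSize`
#' centered at each interior grid point (implemented as box sums of unit
#' plaquette charges, which is exactly the loop winding); centers whose loop
#' charge is +/-1/2 are defect candidates. Candidates closer than `minDist`
#' are merged into single-linkage clusters; each cluster reports its net
#' charge and the plaquette-charge-weighted centroid. Clusters whose net
#' charge is not +/-1/2 (e.g. a tight annihilating pair) are dropped.
#'
#' @param field an [orientation_field] (use the fine sampling, e.g. sigma 10
#'   px and grid size 5 px, for image-derived fields).
#' @param tensorSize loop side length in grid units (default 20).
#' @param minDist merge distance in grid units (default 30).
#' @return object of class `defect_set`: data.frame with `x`, `y` (grid
#'   units), `x_px`, `y_px`, `charge`; attributes `tensorSize`, `minDist`.
#' @export
detect_defects <- function(field, tensorSize = 20, minDist = 30) {
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  if (tensorSize >= min(nr, nc))
    stop("field must be larger than tensorSize")
  q <- plaquette_charges(field)
  q0 <- q; q0[is.na(q0)] <- 0
  idx <- which(abs(q0) > 1e-9, arr.ind = TRUE)
  empty <- data.frame(x = numeric(), y = numeric(), x_px = numeric(),
                      y_px = numeric(), charge = numeric())
  if (nrow(idx) == 0)
    return(structure(empty, tensorSize = tensorSize, minDist = minDist,
                     class = c("defect_set", "data.frame")))
  # candidate cores: charged plaquettes, at their centers (grid units);
  # box sums over tensorSize loops reduce to these plaquettes, so working
  # with them directly is exact and keeps localization sharp
  cand <- data.frame(y = idx[, 1] + 0.5, x = idx[, 2] + 0.5,
                     q = q0[idx])
  # restrict to cores around which a tensorSize loop fits in the lattice
  half <- ceiling(tensorSize / 2)
  inb <- cand$y > half & cand$y <= nr - half & cand$x > half & cand$x <= nc - half
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0)
    return(structure(empty, tensorSize = tensorSize, minDist = minDist,
                     class = c("defect_set", "data.frame")))
  # single-linkage clustering under minDist
  n <- nrow(cand)
  grp <- seq_len(n)
  if (n > 1) {
    D <- as.matrix(stats::dist(cand[, c("x", "y")]))
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        near <- which(D[i, ] < minDist)
        g <- min(grp[near])
        if (any(grp[near] != g)) { grp[near] <- g; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  res <- lapply(split(seq_len(n), grp), function(k) {
    net <- sum(cand$q[k])
    if (abs(abs(net) - 0.5) > 1e-9) return(NULL)
    w <- abs(cand$q[k])
    data.frame(x = sum(cand$x[k] * w) / sum(w),
               y = sum(cand$y[k] * w) / sum(w), charge = net)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    return(structure(empty, tensorSize = tensorSize, minDist = minDist,
                     class = c("defect_set", "data.frame")))
  co <- field_coords(field)
  out <- data.frame(x = res$x, y = res$y,
                    x_px = co$x[1] + (res$x - 1) * field$grid_size,
                    y_px = co$y[1] + (res$y - 1) * field$grid_size,
                    charge = res$charge)
  out <- out[order(out$y, out$x), ]
  rownames(out) <- NULL
  structure(out, tensorSize = tensorSize, minDist = minDist,
            class = c("defect_set", "data.frame"))
}

#' Boundary winding number of a field
#'
#' Winding along the outermost grid loop; equals the total enclosed charge.
#'
#' @param field an [orientation_field].
#' @return list as in [winding_number()].
#' @export
boundary_winding <- function(field) {
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  loop <- rbind(cbind(1, 1:nc), cbind(2:nr, nc),
                cbind(nr, (nc - 1):1), cbind((nr - 1):2, 1))
  winding_number(field, loop)
}

#' Line-integral-convolution rendering of a director field
#'
#' A white-noise texture is averaged along field streamlines traced
#' `streamline_length` unit steps in both directions from every lattice
#' point (direction sign kept continuous along each streamline), then
#' contrast-enhanced by rank histogram equalization with the given power.
#' A second pass can be seeded with the first output for longer coherent
#' streaks.
#'
#' @param field an [orientation_field].
#' @param streamline_length samples traced each way (default 20).
#' @param seed RNG seed for the noise texture.
#' @param passes number of LIC passes (default 1; pass k+1 uses pass k's
#'   output as its texture).
#' @param power histogram-equalization contrast power (default 1.5).
#' @return numeric matrix in `[0, 1]`, same size as the field lattice.
#' @export
lic_render <- function(field, streamline_length = 20, seed = 1, passes = 1,
                       power = 1.5) {
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  c2 <- cos(deg2rad(2 * field$theta)); s2 <- sin(deg2rad(2 * field$theta))
  tex <- with_seed(seed, matrix(stats::runif(nr * nc), nr, nc))
  trace_sum <- function(tex) {
    acc <- as.vector(tex)
    cnt <- rep(1, nr * nc)
    for (dir0 in c(1, -1)) {
      py <- as.vector(matrix(seq_len(nr), nr, nc))
      px <- as.vector(matrix(seq_len(nc), nr, nc, byrow = TRUE))
      # previous unit direction, per streamline
      dc <- interp_bilinear(c2, py, px); ds <- interp_bilinear(s2, py, px)
      ang <- atan2(ds, dc) / 2
      vx <- cos(ang) * dir0; vy <- sin(ang) * dir0
      for (s in seq_len(streamline_length)) {
        px <- px + vx; py <- py + vy
        inside <- px >= 1 & px <= nc & py >= 1 & py <= nr
        pxc <- pmin(pmax(px, 1), nc); pyc <- pmin(pmax(py, 1), nr)
        acc <- acc + ifelse(inside, interp_bilinear(tex, pyc, pxc), 0)
        cnt <- cnt + inside
        # update direction, keeping the sign continuous
        dc <- interp_bilinear(c2, pyc, pxc); ds <- interp_bilinear(s2, pyc, pxc)
        ang <- atan2(ds, dc) / 2
        nx <- cos(ang); ny <- sin(ang)
        flip <- (nx * vx + ny * vy) < 0
        vx <- ifelse(flip, -nx, nx); vy <- ifelse(flip, -ny, ny)
      }
    }
    matrix(acc / cnt, nr, nc)
  }
  out <- tex
  for (p in seq_len(passes)) out <- trace_sum(if (p == 1) tex else out)
  hist_equalize(out, power = power)
}
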