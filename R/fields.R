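#' Orientation field on a regular grid
#'
#' Container for a lattice of nematic angles: `theta` (degrees, `(-90, 90]`)
#' and `coherency` (`[0, 1]`) matrices indexed `[row, col]`, a logical `mask`
#' (`TRUE` = valid vector), the lattice spacing `grid_size` in pixels, the
#' pixel calibration `pixel_size` in micrometres per pixel, and `origin`, the
#' pixel coordinates `(x, y)` of the first grid point.
#'
#' @param theta matrix of angles in degrees; wrapped to the nematic range.
#' @param coherency matrix in `[0, 1]` or a scalar (recycled).
#' @param mask logical matrix, `TRUE` where the vector is valid.
#' @param grid_size lattice spacing in pixels (> 0).
#' @param pixel_size micrometres per pixel (> 0).
#' @param origin numeric length-2, pixel position `(x, y)` of grid point `[1, 1]`.
#' @return an object of class `orientation_field`.
#' @export
orientation_field <- function(theta, coherency = 1, mask = NULL,
                              grid_size = 1, pixel_size = 1,
                              origin = c(grid_size / 2 + 0.5, grid_size / 2 + 0.5)) {
  theta <- as.matrix(theta)
  stopifnot(is.numeric(theta), grid_size > 0, pixel_size > 0)
  if (length(coherency) == 1L) coherency <- matrix(coherency, nrow(theta), ncol(theta))
  coherency <- as.matrix(coherency)
  stopifnot(all(dim(coherency) == dim(theta)),
            all(coherency >= 0 & coherency <= 1, na.rm = TRUE))
  if (is.null(mask)) mask <- !is.na(theta)
  mask <- as.matrix(mask)
  stopifnot(is.logical(mask), all(dim(mask) == dim(theta)))
  theta <- wrap_nematic(theta)
  structure(list(theta = theta, coherency = coherency, mask = mask,
                 grid_size = grid_size, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "orientation_field: %d x %d grid, spacing %.3g px, %.3g um/px, %d/%d valid\n",
    nrow(x$theta), ncol(x$theta), x$grid_size, x$pixel_size,
    sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.orientation_field <- function(x) dim(x$theta)

# pixel coordinates of the grid lattice
field_coords <- function(field) {
  list(x = field$origin[1] + (seq_len(ncol(field$theta)) - 1) * field$grid_size,
       y = field$origin[2] + (seq_len(nrow(field$theta)) - 1) * field$grid_size)
}

#' Rotate all angles of a field by a constant (mod 180)
#'
#' The nematic identification makes global rotation a closed operation on the
#' angle lattice; positions are unchanged.
#'
#' @param field an `orientation_field`.
#' @param alpha rotation in degrees.
#' @return rotated `orientation_field`.
#' @export
rotate_field <- function(field, alpha) {
  field$theta <- wrap_nematic(field$theta + alpha)
  field
}

#' Unmasked angles of a field
#'
#' @param field an `orientation_field`.
#' @return numeric vector of valid angles in degrees.
#' @export
field_angles <- function(field) field$theta[field$mask]
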