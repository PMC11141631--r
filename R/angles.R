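#' Angle conventions and axial-angle helpers
#'
#' Throughout the package images are numeric matrices indexed `[row, col]`;
#' `x` is the column coordinate and `y` the row coordinate, both in pixels.
#' Angles are in degrees, measured counter-clockwise from the +x axis towards
#' +y. Nematic (axial) angles live in `(-90, 90]`: an orientation and its
#' 180-degree rotation are the same axis. Directional angles (migration steps,
#' velocity vectors) live in `(-180, 180]`.
#'
#' @name angle-conventions
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the nematic range (-90, 90]
#'
#' @param theta angles in degrees.
#' @return angles in degrees in `(-90, 90]`, identified modulo 180.
#' @export
wrap_nematic <- function(theta) {
  t <- theta %% 180
  ifelse(t > 90, t - 180, t)
}

#' Wrap angles to the directional range (-180, 180]
#'
#' @param theta angles in degrees.
#' @return angles in degrees in `(-180, 180]`, identified modulo 360.
#' @export
wrap_direction <- function(theta) {
  t <- theta %% 360
  ifelse(t > 180, t - 360, t)
}

#' Doubled-angle (axial) circular mean and resultant length
#'
#' Axial angles are doubled, averaged as unit vectors, and halved again.
#' The resultant length of the doubled-angle vectors is the standard 2D
#' nematic order parameter of the sample.
#'
#' @param theta axial angles in degrees.
#' @param w optional non-negative weights.
#' @return list with `mean` (degrees, in (-90, 90]) and `R` (resultant
#'   length in `[0, 1]`).
#' @export
axial_mean <- function(theta, w = NULL) {
  if (length(theta) == 0L) stop("no angles supplied")
  t2 <- deg2rad(2 * theta)
  if (is.null(w)) {
    C <- mean(cos(t2)); S <- mean(sin(t2))
  } else {
    if (any(w < 0)) stop("weights must be non-negative")
    sw <- sum(w)
    if (sw == 0) stop("all weights are zero")
    C <- sum(w * cos(t2)) / sw; S <- sum(w * sin(t2)) / sw
  }
  list(mean = wrap_nematic(rad2deg(atan2(S, C)) / 2), R = sqrt(C^2 + S^2))
}

# Smallest nematic difference a-b mapped to (-90, 90].
nematic_diff <- function(a, b) wrap_nematic(a - b)
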