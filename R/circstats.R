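# Circular statistics for comparing angular samples between conditions:
# axial-to-circular doubling and the Watson-Wheeler (Mardia) test for
# homogeneity.

#' Angular sample
#'
#' A vector of angles in degrees tagged as `axial` (defined mod 180, stored
#' in `(-90, 90]`) or `directional` (mod 360, stored in `(-180, 180]`) with a
#' group label.
#'
#' @param angles angles in degrees.
#' @param kind `"axial"` or `"directional"`.
#' @param group group label (character scalar).
#' @return object of class `angular_sample`.
#' @export
angular_sample <- function(angles, kind = c("axial", "directional"),
                           group = "sample") {
  kind <- match.arg(kind)
  angles <- if (kind == "axial") wrap_nematic(angles) else wrap_direction(angles)
  structure(list(angles = as.numeric(angles), kind = kind,
                 group = as.character(group)),
            class = "angular_sample")
}

#' Double an axial sample onto the full circle
#'
#' Axial data are doubled (and wrapped to `(-180, 180]`) before circular
#' tests, the standard device that maps the mod-180 identification onto the
#' circle. Applying it to a directional sample is an error.
#'
#' @param sample an `angular_sample` of kind `"axial"`.
#' @return an `angular_sample` of kind `"directional"` with doubled angles.
#' @export
axial_to_circular <- function(sample) {
  stopifnot(inherits(sample, "angular_sample"))
  if (sample$kind != "axial")
    stop("axial_to_circular expects an axial sample")
  angular_sample(wrap_direction(2 * sample$angles), "directional",
                 sample$group)
}

#' Watson-Wheeler test for homogeneity of angular samples
#'
#' Large-sample uniform-scores test: the pooled angles are ranked around the
#' circle, each observation is assigned the uniform score
#' `beta = 2 * pi * rank / N`, and
#' `W = sum_i 2 (C_i^2 + S_i^2) / n_i` with `C_i`, `S_i` the per-group sums
#' of `cos(beta)`, `sin(beta)`. Under homogeneity W is asymptotically
#' chi-squared with `2 (k - 1)` degrees of freedom. Axial samples are
#' doubled first (set `double_axial = FALSE` to disable). Rank ties are
#' broken by a small seeded jitter, reported in the result. Groups need
#' n >= 10 for the approximation; smaller groups are rejected.
#'
#' @param samples list of `angular_sample`s (>= 2, same kind), or a
#'   data.frame with columns `angle_deg` and `group`.
#' @param kind used when `samples` is a data.frame (default `"axial"`).
#' @param double_axial double axial angles before testing (default TRUE).
#' @param seed seed for tie-breaking jitter (default 1).
#' @return object of class `htest`: `statistic` (W), `parameter` (df),
#'   `p.value`, `method`, plus `jitter_seed`.
#' @export
watson_wheeler <- function(samples, kind = "axial", double_axial = TRUE,
                           seed = 1) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("angle_deg", "group") %in% names(samples)))
    samples <- lapply(split(samples$angle_deg, samples$group),
                      function(a) angular_sample(a, kind,
                                                 group = "split"))
  }
  stopifnot(length(samples) >= 2,
            all(vapply(samples, inherits, logical(1), "angular_sample")))
  kinds <- vapply(samples, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1) stop("all samples must share a kind")
  if (kinds[1] == "axial" && double_axial)
    samples <- lapply(samples, axial_to_circular)
  n_i <- vapply(samples, function(s) length(s$angles), numeric(1))
  if (any(n_i < 10))
    stop("each group needs at least 10 observations")
  ang <- unlist(lapply(samples, `[[`, "angles"))
  grp <- rep(seq_along(samples), n_i)
  N <- length(ang)
  if (anyDuplicated(ang)) {
    ang <- ang + with_seed(seed, stats::runif(N, -1e-6, 1e-6))
  }
  beta <- 2 * pi * rank(ang) / N
  W <- sum(vapply(seq_along(samples), function(i) {
    b <- beta[grp == i]
    2 * (sum(cos(b))^2 + sum(sin(b))^2) / n_i[i]
  }, numeric(1)))
  df <- 2 * (length(samples) - 1)
  p <- stats::pchisq(W, df, lower.tail = FALSE)
  structure(list(statistic = c(W = W), parameter = c(df = df), p.value = p,
                 method = "Watson-Wheeler test for homogeneity of angles",
                 data.name = paste(length(samples), "groups, n =",
                                   paste(n_i, collapse = ", ")),
                 jitter_seed = seed),
            class = "htest")
}
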