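make_texture <- function(seed = 3, n = 256) {
  fld <- gen_correlated_field(c(n / 16, n / 16), 3, seed = seed,
                              grid_size = 16)
  gen_filament_image(fld, filament_length = 12, filament_density = 0.03,
                     seed = seed + 100)
}

test_that("preprocessing stretches to full range and is stable on good input", {
  grad <- matrix(rep(seq(0.4, 0.6, length.out = 128), 128), 128)
  out <- piv_preprocess(grad)
  expect_equal(range(out), c(0, 1))
  # an already well-spread image keeps its ordering and range
  set.seed(2)
  img <- matrix(runif(128 * 128), 128)
  out2 <- piv_preprocess(img)
  expect_equal(range(out2), c(0, 1))
  expect_gt(cor(as.vector(img), as.vector(out2)), 0.98)
})

test_that("single-pass PIV recovers integer and subpixel constant shifts", {
  img <- make_texture()
  pair <- gen_displaced_pair(img, c(5, 3))
  vf <- piv_pass(pair$a, pair$b, 64, 32)
  expect_lt(max(abs(vf$u[vf$valid] - 5)), 0.1)
  expect_lt(max(abs(vf$v[vf$valid] - 3)), 0.1)
  # identical frames: zero field
  vf0 <- piv_pass(img, img, 64, 32)
  expect_lt(max(abs(c(vf0$u, vf0$v))), 1e-6)
  # subpixel shift via the 3-point Gaussian fit (interior windows; sharp
  # speckle autocorrelation peak, the texture subpixel PIV is rated on)
  spk <- gen_speckle_image(256, seed = 21)
  pair2 <- gen_displaced_pair(spk, c(2.5, 0))
  vf2 <- piv_pass(pair2$a, pair2$b, 64, 32)
  inner <- vf2$valid; inner[c(1, nrow(inner)), ] <- FALSE
  inner[, c(1, ncol(inner))] <- FALSE
  expect_lt(max(abs(vf2$u[inner] - 2.5)), 0.2)
  expect_lt(max(abs(vf2$v[inner])), 0.2)
  expect_error(piv_pass(img, img, 8, 8), ">= 16")
  expect_error(piv_pass(img, img, 512, 8), "larger than image")
})

test_that("swapping the frames negates the displacement", {
  img <- make_texture(seed = 7)
  pair <- gen_displaced_pair(img, c(4, -2))
  fwd <- piv_pass(pair$a, pair$b, 64, 32)
  bwd <- piv_pass(pair$b, pair$a, 64, 32)
  ok <- fwd$valid & bwd$valid
  expect_lt(max(abs(fwd$u[ok] + bwd$u[ok])), 0.2)
  expect_lt(max(abs(fwd$v[ok] + bwd$v[ok])), 0.2)
})

test_that("multipass reduces to a single pass and calibrates units", {
  img <- make_texture(seed = 9)
  pair <- gen_displaced_pair(img, c(3, 1))
  single <- piv_pass(pair$a, pair$b, 64, 32)
  multi <- piv_multipass(pair$a, pair$b, list(c(64, 32)),
                         frame_interval = 3, pixel_size = 0.65)
  expect_equal(multi$u, single$u, tolerance = 1e-12)
  expect_equal(multi$v, single$v, tolerance = 1e-12)
  # 1 px/frame at 0.65 um/px and 3 h interval is 0.2167 um/hour
  expect_equal(unique(round(as.vector(multi$u_umh / multi$u), 6)),
               round(0.65 / 3, 6))
  # boundary ring flagged invalid
  expect_false(any(multi$valid[1, ]))
  expect_false(any(multi$valid[, 1]))
  expect_error(piv_multipass(pair$a, pair$b, list(c(64, 32), c(64, 32))),
               "decreasing")
})

test_that("multipass recovers a smooth shear flow", {
  img <- gen_speckle_image(256, seed = 11)
  n <- nrow(img)
  uu <- matrix(rep(seq(0, 6, length.out = n), ncol(img)), n)
  pair <- gen_displaced_pair(img, list(u = uu, v = matrix(0, n, ncol(img))))
  vf <- piv_multipass(pair$a, pair$b, list(c(128, 64), c(64, 32)))
  truth <- matrix(rep((vf$y - 1) / (n - 1) * 6, length(vf$x)), length(vf$y))
  err <- (vf$u - truth)[vf$valid]
  expect_lt(sqrt(mean(err^2)), 0.3)
  expect_lt(sqrt(mean(vf$v[vf$valid]^2)), 0.3)
})

test_that("flow statistics reuse the nematic correlation pipeline", {
  # uniform flow: C is identically 1, xi degenerate-flagged
  mkvf <- function(u, v, valid = NULL) {
    if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
    velocity_field(u, v, x = seq_len(ncol(u)) * 32, y = seq_len(nrow(u)) * 32,
                   valid = valid, window = 64, step = 32,
                   frame_interval = 1, pixel_size = 1)
  }
  uni <- mkvf(matrix(3, 10, 10), matrix(2, 10, 10))
  fs <- flow_statistics(list(uni))
  expect_true(fs$degenerate[1])
  expect_equal(fs$mean_speed_umh[1], sqrt(13), tolerance = 1e-9)
  # i.i.d. angles: xi close to the ideal-curve intercept (a few grid steps)
  set.seed(5)
  ang <- matrix(runif(400, -pi, pi), 20, 20)
  iid <- mkvf(cos(ang), sin(ang))
  fs2 <- flow_statistics(list(iid))
  expect_lt(fs2$xi_vv_um[1], 4 * 32)
  # shared-code identity: xi_vv equals the nemorder pipeline on the angles
  fld <- orientation_field(wrap_nematic(ang * 180 / pi), grid_size = 32,
                           pixel_size = 1, origin = c(32, 32))
  xi_direct <- correlation_length(nematic_autocorrelation(fld))$xi_um
  expect_equal(fs2$xi_vv_um[1], xi_direct, tolerance = 1e-12)
  # two half-domains at +/-40 degrees: xi finite, below the domain width,
  # and in agreement with the dense-pair oracle on the same angle lattice
  ang2 <- matrix(0, 20, 20)
  ang2[, 1:10] <- 40; ang2[, 11:20] <- -40
  dom <- mkvf(cos(deg2rad(ang2)), sin(deg2rad(ang2)))
  fs3 <- flow_statistics(list(dom))
  expect_gt(fs3$xi_vv_um[1], 2 * 32)
  expect_lt(fs3$xi_vv_um[1], 20 * 32)
  fdom <- orientation_field(ang2, grid_size = 32)
  cur <- nematic_autocorrelation(fdom)
  oracle <- dense_xi_oracle(fdom, dmax_px = cur$d_px[10])
  expect_lt(abs(fs3$xi_vv_um[1] - oracle) / oracle, 0.15)
  # artifact frames dropped
  fs4 <- flow_statistics(list(uni, uni, uni), artifact_frames = 2)
  expect_equal(fs4$frame, c(1, 3))
})
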