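test_that("global order parameter has the right limits and closed form", {
  expect_equal(global_order(gen_uniform_field(c(8, 8), 37)), 1)
  expect_equal(global_order(c(0, 90)), 0, tolerance = 1e-12)
  set.seed(3)
  expect_lt(global_order(runif(1e4, -90, 90)), 0.05)
  # Eq-form equals the doubled-angle resultant length (closed-form oracle)
  for (s in 1:10) {
    set.seed(s)
    ang <- runif(50, -90, 90)
    expect_equal(global_order(ang), axial_mean(ang)$R, tolerance = 1e-12)
  }
  # invariance under global rotation and the nematic identification
  set.seed(4)
  f <- gen_correlated_field(c(12, 12), 2, seed = 4)
  expect_equal(global_order(rotate_field(f, 57.3)), global_order(f),
               tolerance = 1e-9)
  expect_equal(global_order(f$theta + 180), global_order(f),
               tolerance = 1e-12)
  expect_error(global_order(orientation_field(matrix(NA_real_, 3, 3))),
               "unmasked")
})

test_that("local order windows match the literal per-window computation", {
  u <- local_order_map(gen_uniform_field(c(10, 10), 15))
  expect_true(all(u$local_S == 1))
  # sharp 0/90 wall: straddling windows depressed, pure windows perfect
  th <- cbind(matrix(0, 8, 4), matrix(90, 8, 4))
  om <- local_order_map(orientation_field(th))
  expect_true(all(om$local_S[, 1] == 1))
  expect_true(all(om$local_S[, 5] == 1))
  expect_true(all(om$local_S[, 2:4] < 0.6))
  # oracle equality on i.i.d. fields
  set.seed(7)
  f <- orientation_field(matrix(runif(144, -90, 90), 12, 12))
  om2 <- local_order_map(f)
  for (i in seq_len(nrow(om2$local_S))) {
    for (j in seq_len(ncol(om2$local_S))) {
      expect_equal(om2$local_S[i, j],
                   brute_window_S(as.vector(f$theta[i:(i + 3), j:(j + 3)])),
                   tolerance = 1e-12)
    }
  }
  expect_error(local_order_map(gen_uniform_field(c(3, 3), 0)), "smaller")
})

test_that("spatial disorder counts sub-threshold windows", {
  expect_equal(spatial_disorder(local_order_map(gen_uniform_field(c(8, 8), 0))), 0)
  set.seed(8)
  f <- orientation_field(matrix(runif(400, -90, 90), 20, 20))
  om <- local_order_map(f)
  brute <- sapply(seq_len(nrow(om$local_S)), function(i) {
    sapply(seq_len(ncol(om$local_S)), function(j) {
      brute_window_S(as.vector(f$theta[i:(i + 3), j:(j + 3)])) < 0.5
    })
  })
  expect_equal(spatial_disorder(om), 100 * mean(brute))
  expect_equal(spatial_disorder(om, threshold = 1 + 1e-9), 100)
})

test_that("autocorrelation matches the O(N^2) oracle in both binning modes", {
  for (s in 1:4) {
    set.seed(20 + s)
    n <- sample(12:16, 1)
    f <- orientation_field(matrix(runif(n * n, -90, 90), n, n))
    for (b in c("exact", "grid")) {
      cur <- nematic_autocorrelation(f, binning = b)
      oracle <- brute_autocorr(f, binning = b)
      expect_equal(cur$d_grid, oracle$d_grid, tolerance = 1e-12)
      expect_equal(cur$C, oracle$C, tolerance = 1e-12)
    }
  }
})

test_that("masked vectors are excluded pairwise", {
  set.seed(31)
  th <- matrix(runif(196, -90, 90), 14, 14)
  mask <- matrix(runif(196) > 0.3, 14, 14)
  f <- orientation_field(th, mask = mask)
  cur <- nematic_autocorrelation(f)
  oracle <- brute_autocorr(f)
  expect_equal(cur$C, oracle$C, tolerance = 1e-12)
})

test_that("FFT and direct lag paths agree on larger fields", {
  f <- gen_correlated_field(c(40, 40), 3, seed = 5) # 1600 points: FFT path
  cur_fft <- nematic_autocorrelation(f)
  # force the direct path on the same field by splitting is impossible;
  # instead compare against the brute-force oracle on a 20x20 crop and the
  # full-field FFT result restricted to the crop's support via a second
  # 20x20 field object (the two algorithms must agree wherever both run)
  crop <- orientation_field(f$theta[1:20, 1:20])
  expect_equal(nematic_autocorrelation(crop)$C, brute_autocorr(crop)$C,
               tolerance = 1e-12)
  # sanity on the FFT result itself
  expect_equal(cur_fft$C[cur_fft$d_grid == 0], 1)
  expect_true(all(cur_fft$C >= -1 - 1e-9 & cur_fft$C <= 1 + 1e-9))
})

test_that("uniform and checkerboard fields give the textbook curves", {
  cu <- nematic_autocorrelation(gen_uniform_field(c(10, 10), 42))
  expect_true(all(abs(cu$C - 1) < 1e-12))
  cb <- outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 0, 90))
  cc <- nematic_autocorrelation(orientation_field(cb))
  expect_equal(cc$C[cc$d_grid == 0], 1)
  expect_equal(cc$C[cc$d_grid == 1], -1)
})

test_that("correlation length is the x-intercept, with units and degeneracy", {
  # exact line through the first 10 classes (curve extends past the fit)
  line <- structure(
    data.frame(d_grid = 0:12, d_px = 0:12, d_um = 0:12, C = 1 - (0:12) / 10,
               n_pairs = 1),
    grid_size = 1, pixel_size = 1,
    class = c("correlation_curve", "data.frame"))
  xi <- correlation_length(line)
  expect_equal(xi$xi_px, 10, tolerance = 1e-12)
  expect_false(xi$degenerate)
  # pixel-size conversion: 1000 px at 0.65 um/px is 650 um
  big <- structure(
    data.frame(d_grid = 0:14, d_px = (0:14) * 100, d_um = (0:14) * 65,
               C = 1 - (0:14) / 10, n_pairs = 1),
    grid_size = 100, pixel_size = 0.65,
    class = c("correlation_curve", "data.frame"))
  xib <- correlation_length(big)
  expect_equal(xib$xi_px, 1000, tolerance = 1e-9)
  expect_equal(xib$xi_um, 650, tolerance = 1e-9)
  # uniform field: slope 0, flagged and clamped to the largest distance
  cu <- nematic_autocorrelation(gen_uniform_field(c(10, 10), 0))
  xiu <- correlation_length(cu)
  expect_true(xiu$degenerate)
  expect_equal(xiu$xi_px, max(cu$d_px))
  expect_error(correlation_length(line[1, ]), "at least 2")
})

test_that("order heatmaps scale local S onto 8-bit gray", {
  om <- local_order_map(gen_uniform_field(c(6, 6), 10))
  g <- order_map_gray(om)
  expect_true(is.integer(g))
  expect_true(all(g == 255L))
})
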