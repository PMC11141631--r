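test_that("uniform field generator gives perfect order and checks its domain", {
  f <- gen_uniform_field(c(16, 16), 30)
  expect_true(all(f$theta == 30))
  expect_true(all(f$coherency == 1))
  expect_equal(global_order(f), 1)
  f0 <- gen_uniform_field(c(16, 16), 0)
  expect_true(all(f0$theta == 0))
  expect_error(gen_uniform_field(c(16, 16), 90.0001), "nematic range")
})

test_that("generators are seed-deterministic and leave the RNG alone", {
  set.seed(42); before <- runif(1)
  set.seed(42)
  a <- gen_correlated_field(c(24, 24), 3, seed = 7)
  b <- gen_correlated_field(c(24, 24), 3, seed = 7)
  expect_identical(a, b)
  img1 <- gen_filament_image(gen_uniform_field(c(8, 8), 20, grid_size = 8),
                             seed = 5)
  img2 <- gen_filament_image(gen_uniform_field(c(8, 8), 20, grid_size = 8),
                             seed = 5)
  expect_identical(img1, img2)
  g1 <- gen_growth_tracks(n_frames = 6, field_size_px = 120, seed = 3,
                          render = FALSE)
  g2 <- gen_growth_tracks(n_frames = 6, field_size_px = 120, seed = 3,
                          render = FALSE)
  expect_identical(g1$tracks, g2$tracks)
  # generator calls above must not perturb the caller's RNG stream
  expect_identical(runif(1), before)
})

test_that("correlated-field smoothing controls the correlation length", {
  # scale 0: i.i.d. angles, correlation dies beyond distance zero; the
  # fitted intercept then equals the closed-form intercept of the ideal
  # curve C(0) = 1, C(d > 0) = 0 over the same 10 distance classes
  f0 <- gen_correlated_field(c(30, 30), 0, seed = 1)
  cur <- nematic_autocorrelation(f0)
  expect_lt(abs(cur$C[cur$d_grid == 1]), 0.15)
  xi <- correlation_length(cur)
  d10 <- cur$d_grid[1:10]
  ideal <- lm(c(1, rep(0, 9)) ~ d10)
  xi_ideal <- -coef(ideal)[1] / coef(ideal)[2]
  expect_lt(abs(xi$xi_grid - xi_ideal), 0.5)
  # very large scale: near-uniform field, S -> 1
  fbig <- gen_correlated_field(c(24, 24), 32, seed = 2)
  expect_gt(global_order(fbig), 0.99)
  # monotonicity of xi in the smoothing scale (Spearman over seeds x scales)
  scales <- c(1, 2, 4, 6, 8)
  grid <- expand.grid(seed = 1:20, scale = scales)
  grid$xi <- mapply(function(s, sc) {
    f <- gen_correlated_field(c(30, 30), sc, seed = s)
    correlation_length(nematic_autocorrelation(f))$xi_grid
  }, grid$seed, grid$scale)
  rho <- cor(grid$scale, grid$xi, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("defect fields carry the planted winding", {
  f <- gen_defect_field(c(64, 64), data.frame(x = 32.5, y = 32.5, charge = 0.5))
  w <- winding_number(f, cellnematics:::square_loop(32, 32, 10))
  expect_equal(w$charge, 0.5)
  expect_lt(abs(w$residual), 1e-6)
  # charge additivity: loop enclosing a +1/2 -1/2 pair winds to zero
  fp <- gen_defect_field(c(64, 64), data.frame(x = c(26.5, 38.5),
                                               y = c(32.5, 32.5),
                                               charge = c(0.5, -0.5)))
  wp <- winding_number(fp, cellnematics:::square_loop(32, 32, 20))
  expect_equal(wp$charge, 0)
  # empty defect list: uniform field
  fu <- gen_defect_field(c(16, 16), NULL, theta0 = 12)
  expect_true(all(fu$theta == 12))
  expect_error(
    gen_defect_field(c(32, 32), data.frame(x = c(10, 10), y = c(10, 10),
                                           charge = c(0.5, -0.5))),
    "coincident")
  expect_error(
    gen_defect_field(c(32, 32), data.frame(x = 10, y = 10, charge = 1)),
    "charges")
})

test_that("boundary winding equals the sum of planted charges (property)", {
  for (s in 1:8) {
    set.seed(100 + s)
    k <- sample(1:3, 1)
    pts <- separated_points(k, 12, 52, 12)
    ch <- sample(c(-0.5, 0.5), k, replace = TRUE)
    f <- gen_defect_field(c(64, 64),
                          data.frame(x = pts[, 1] + 0.5, y = pts[, 2] + 0.5,
                                     charge = ch))
    w <- boundary_winding(f)
    expect_equal(w$charge, sum(ch))
    expect_lt(abs(w$residual), 1e-6)
  }
})

test_that("filament images carry the director orientation of their field", {
  fld <- gen_uniform_field(c(16, 16), 30, grid_size = 16)
  img <- gen_filament_image(fld, filament_length = 15,
                            filament_density = 0.03, seed = 11)
  pm <- structure_tensor(img, sigma_window = 10)
  ok <- !is.na(pm$theta) & pm$coherency >= 0.25
  recovered <- axial_mean(pm$theta[ok], w = pm$coherency[ok])$mean
  expect_lt(abs(recovered - 30), 2)
  # zero density: blank image
  blank <- gen_filament_image(fld, filament_density = 0, seed = 1)
  expect_true(all(blank == 0))
})

test_that("displaced pairs implement the stated flow", {
  fld <- gen_correlated_field(c(16, 16), 4, seed = 3, grid_size = 8)
  img <- gen_filament_image(fld, filament_density = 0.03, seed = 4)
  same <- gen_displaced_pair(img, c(0, 0))
  expect_equal(same$a, same$b, tolerance = 1e-10)
  # integer constant shift: pixels move exactly (Fourier shift is exact)
  sh <- gen_displaced_pair(img, c(5, 3))
  expect_equal(sh$b[10:100, 10:100], img[(10:100) - 3, (10:100) - 5],
               tolerance = 1e-8)
})

test_that("growth simulation plateaus at carrying capacity and tracks are well-formed", {
  g <- gen_growth_tracks(n_frames = 40, frame_interval = 3,
                         field_size_px = 300, capacity = 4000, rate = 0.05,
                         seed = 6, render = FALSE)
  plateau <- tail(g$density$density, 1)
  expect_lt(abs(plateau - 4000) / 4000, 0.05)
  ts <- g$tracks
  expect_s3_class(ts, "track_set")
  expect_true(all(ts$x_um >= 0 & ts$x_um <= 300))
  bad <- tapply(ts$frame, ts$track_id, function(f) any(diff(f) <= 0))
  expect_false(any(unlist(bad)))
})
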