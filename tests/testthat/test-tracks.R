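test_that("nuclei detection finds separated spots and applies the size gate", {
  set.seed(9)
  pts <- separated_points(60, 20, 364, 26)
  img <- cellnematics:::render_spots(384, pts[, 1], pts[, 2], 12 / 2.355)
  det <- detect_nuclei(img, pixel_size = 1)
  expect_equal(nrow(det), 60)
  D <- sqrt(outer(det$x_px, pts[, 1], "-")^2 + outer(det$y_px, pts[, 2], "-")^2)
  expect_lt(max(apply(D, 2, min)), 1)
  # blank frame: nothing
  expect_equal(nrow(detect_nuclei(matrix(0, 128, 128), 1)), 0)
  # oversized spot excluded by the 6-30 um diameter gate
  big <- cellnematics:::render_spots(200, 100, 100, 40 / 2.355)
  expect_equal(nrow(detect_nuclei(big, 1)), 0)
  # same spot at half pixel size (80 um apparent) also excluded; at
  # 0.25 um/px it reads 10 um and is kept
  expect_equal(nrow(detect_nuclei(big, 0.25)), 1)
})

test_that("greedy mutual-nearest-neighbour linking behaves at the edges", {
  # single frame: singleton tracks
  one <- link_tracks(list(data.frame(x_um = c(1, 5), y_um = c(1, 5))),
                     max_disp = 2)
  expect_equal(nrow(one), 2)
  expect_equal(sort(unique(one$track_id)), c(1, 2))
  # both points jump beyond max_disp: tracks terminated, two new ones
  swap <- link_tracks(list(
    data.frame(x_um = c(0, 100), y_um = c(0, 0)),
    data.frame(x_um = c(50, 150), y_um = c(50, 50))),
    max_disp = 20)
  expect_equal(length(unique(swap$track_id)), 4)
  # non-crossing random walkers: all links correct
  set.seed(11)
  start <- separated_points(40, 10, 290, 30)
  pos <- start
  frames <- list(data.frame(x_um = pos[, 1], y_um = pos[, 2]))
  for (f in 2:6) {
    pos <- pos + matrix(runif(80, -3, 3), 40, 2)
    frames[[f]] <- data.frame(x_um = pos[, 1], y_um = pos[, 2])
  }
  lt <- link_tracks(frames, max_disp = 12)
  expect_equal(length(unique(lt$track_id)), 40)
  expect_equal(nrow(lt), 40 * 6)
})

test_that("cell density and aligned time follow the stated conventions", {
  expect_equal(cell_density(list(data.frame(x_um = runif(400),
                                            y_um = runif(400))),
                            field_area_mm2 = 0.1)$density, 4000)
  expect_equal(cell_density(list(data.frame(x_um = numeric(),
                                            y_um = numeric())),
                            field_area_mm2 = 0.1)$density, 0)
  # peak at raw t = 60 h aligns with offset -24 h
  tt <- seq(0, 90, by = 3)
  dens <- data.frame(t_h = tt, density = 4000 * exp(-((tt - 60) / 20)^2))
  al <- align_time_series(dens, target_peak = 36)
  expect_equal(attr(al, "offset_h"), -24)
  expect_equal(al$t_a, tt - 24)
  # two replicates generated with a 9 h lag align to within one frame
  d2 <- data.frame(t_h = tt, density = 4000 * exp(-((tt - 69) / 20)^2))
  al2 <- align_time_series(d2, target_peak = 36)
  expect_lte(abs(al$t_a[which.max(al$density_smooth)] -
                   al2$t_a[which.max(al2$density_smooth)]), 3)
  # flat series flagged with zero offset
  expect_message(alf <- align_time_series(
    data.frame(t_h = 0:5, density = rep(7, 6))), "flat")
  expect_equal(attr(alf, "offset_h"), 0)
  expect_true(attr(alf, "flagged"))
  # still-rising series flagged
  expect_message(align_time_series(
    data.frame(t_h = 0:5, density = 1:6)), "rising")
})

test_that("migration statistics measure speed and direction per step", {
  ts <- track_set(data.frame(track_id = 1, frame = 1:5, t_h = 0:4,
                             x_um = seq(0, 40, by = 10), y_um = 0),
                  frame_interval = 1, field_area_mm2 = 1)
  ms <- migration_stats(ts)
  expect_equal(ms$steps$speed_umh, rep(10, 4))
  expect_equal(ms$steps$angle_deg, rep(0, 4))
  expect_equal(ms$cells$mean_speed_umh, 10)
  # zero-length steps: speed 0, no angle
  ts0 <- track_set(data.frame(track_id = 1, frame = 1:3, t_h = 0:2,
                              x_um = c(0, 0, 3), y_um = 0),
                   frame_interval = 1, field_area_mm2 = 1)
  st <- migration_stats(ts0)$steps
  expect_equal(st$speed_umh, c(0, 3))
  expect_true(is.na(st$angle_deg[1]))
  # speeds invariant under global rotation/translation of coordinates
  set.seed(3)
  d <- data.frame(track_id = rep(1:5, each = 4), frame = rep(1:4, 5),
                  t_h = rep(0:3, 5), x_um = runif(20, 0, 50),
                  y_um = runif(20, 0, 50))
  a <- deg2rad(33)
  rot <- data.frame(track_id = d$track_id, frame = d$frame, t_h = d$t_h,
                    x_um = 5 + d$x_um * cos(a) - d$y_um * sin(a),
                    y_um = -2 + d$x_um * sin(a) + d$y_um * cos(a))
  s1 <- migration_stats(track_set(d, 1, 1))$steps
  s2 <- migration_stats(track_set(rot, 1, 1))$steps
  expect_equal(s1$speed_umh, s2$speed_umh, tolerance = 1e-9)
  expect_equal(wrap_direction(s2$angle_deg - s1$angle_deg),
               rep(33, nrow(s1)), tolerance = 1e-9)
})

test_that("normalized directional migration has the stated limits", {
  set.seed(5)
  r <- normalized_directional_migration(runif(2e5, -180, 180))
  expect_lt(abs(r$ratio - 1), 0.05)
  expect_equal(normalized_directional_migration(rep(5, 100))$ratio, 9)
  expect_equal(normalized_directional_migration(rep(175, 100))$ratio, 0)
  expect_equal(r$denominator, 2 / 18)
  # equivariance: rotating both steps and director leaves the ratio alone
  ang <- runif(500, -180, 180)
  expect_equal(normalized_directional_migration(ang, director = 0)$ratio,
               normalized_directional_migration(
                 wrap_direction(ang + 47), director = 47)$ratio)
})

test_that("bias strength maps monotonically onto the directional ratio", {
  biases <- c(0, 0.3, 0.8, 2, 6)
  ratios <- sapply(seq_along(biases), function(i) {
    g <- gen_growth_tracks(n_frames = 25, field_size_px = 250,
                           capacity = 1500, rate = 0.1, bias = biases[i],
                           seed = 40 + i, render = FALSE)
    st <- migration_stats(g$tracks)$steps
    normalized_directional_migration(st$angle_deg)$ratio
  })
  expect_gt(cor(biases, ratios, method = "spearman"), 0.9)
  expect_true(all(diff(ratios) > -0.05))
})

test_that("speed-density profiles average replicate interpolations", {
  r1 <- data.frame(density = c(100, 200, 300), value = c(10, 8, 6))
  r2 <- data.frame(density = c(150, 250, 350), value = c(9, 7, 5))
  pr <- density_profile_average(list(r1, r2), increment = 10, min_n = 2)
  # hand-computed: at 200 cells/mm^2, replicate 1 gives 8, replicate 2
  # interpolates to 8; mean 8
  expect_equal(pr$mean_value[pr$density == 200], 8)
  expect_equal(pr$mean_value[pr$density == 250],
               mean(c(approx(r1$density, r1$value, 250)$y, 7)))
  expect_true(all(pr$density %% 10 == 0))
})

test_that("division axes are folded to the nematic range and binned", {
  h <- division_axis(data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 0))
  expect_equal(h$frequency[h$bin_lo < 0 & h$bin_hi >= 0], 1)
  # vertical pair lands in the (70, 90] boundary bin under the folding rule
  hv <- division_axis(data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 10))
  expect_equal(hv$frequency[hv$bin_hi == 90], 1)
  expect_error(division_axis(data.frame(x1 = 1, y1 = 1, x2 = 1, y2 = 1)),
               "coincident")
  set.seed(8)
  a <- runif(5e4, 0, pi)
  hu <- division_axis(data.frame(x1 = 0, y1 = 0, x2 = cos(a), y2 = sin(a)))
  expect_true(all(abs(hu$frequency - 1 / 9) < 0.02))
})

test_that("track tables round-trip through CSV including TrackMate exports", {
  g <- gen_growth_tracks(n_frames = 5, field_size_px = 100, seed = 2,
                         render = FALSE)
  p <- tempfile(fileext = ".csv")
  write_tracks_csv(g$tracks, p)
  back <- read_tracks_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(g$tracks))
  expect_equal(attr(back, "field_area_mm2"), attr(g$tracks, "field_area_mm2"))
  # TrackMate-style spot export maps onto the canonical schema
  tm <- data.frame(TRACK_ID = c(0, 0, 1), FRAME = c(0, 1, 0),
                   POSITION_X = c(1, 2, 3), POSITION_Y = c(4, 5, 6))
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(tm, p2, row.names = FALSE)
  ts <- read_tracks_csv(p2, frame_interval = 0.5, field_area_mm2 = 2)
  expect_equal(ts$track_id, c(1, 1, 2))
  expect_equal(ts$t_h, c(0, 0.5, 0))
  expect_equal(ts$x_um, c(1, 2, 3))
  unlink(c(p, p2))
})
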