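test_that("identical configs are bit-reproducible", {
  cfg <- sim_config(seed = 77, n_frames = 300)
  a <- simulate_dataset(cfg, geo)
  b <- simulate_dataset(cfg, geo)
  expect_identical(a$truth$points, b$truth$points)
  expect_identical(as.data.frame(a$top_stream), as.data.frame(b$top_stream))
  expect_identical(as.data.frame(a$side_stream), as.data.frame(b$side_stream))
  c <- simulate_trajectory(sim_config(seed = 78, n_frames = 300), tank)
  expect_false(identical(a$truth$points$x_cm, c$points$x_cm))
})

test_that("persistence 1 gives a straight line until wall reflection", {
  cfg <- sim_config(seed = 1, n_frames = 400, persistence = 1,
                    mean_speed_cm_s = 10, init_heading = c(1, 0, 0))
  tr <- simulate_trajectory(cfg, tank)
  p <- tr$points
  # starts at the tank center moving +x at 1 cm/frame; wall at 43 cm
  expect_equal(p$y_cm, rep(tank$width_y_cm / 2, 400))
  expect_equal(p$z_cm, rep(tank$height_z_cm / 2, 400))
  expect_equal(diff(p$x_cm[1:20]), rep(1, 19))
  # sampled maximum is within one step of the wall, then motion reverses
  expect_gt(max(p$x_cm), tank$length_x_cm - 1)
  after <- which.max(p$x_cm)
  expect_equal(diff(p$x_cm)[(after + 1):(after + 5)], rep(-1, 5))
  expect_true(all(p$x_cm >= 0 & p$x_cm <= tank$length_x_cm))
})

test_that("trajectories stay inside the tank", {
  for (seed in 1:5) {
    tr <- simulate_trajectory(sim_config(seed = seed, n_frames = 2000), tank)
    p <- tr$points
    expect_true(all(p$x_cm >= 0 & p$x_cm <= tank$length_x_cm))
    expect_true(all(p$y_cm >= 0 & p$y_cm <= tank$width_y_cm))
    expect_true(all(p$z_cm >= 0 & p$z_cm <= tank$height_z_cm))
  }
})

test_that("projection to views round-trips through the calibration", {
  set.seed(81)
  n <- 1000
  pts <- data.frame(frame_index = 0:(n - 1), timestamp_s = (0:(n - 1)) * 0.1,
                    x_cm = runif(n, 0, tank$length_x_cm),
                    y_cm = runif(n, 0, tank$width_y_cm),
                    z_cm = runif(n, 0, tank$height_z_cm))
  truth <- trajectory(pts)
  boxes <- project_to_views(truth, cams, tank)
  top_ctr <- bbox_center_px(boxes$top, cams$top)
  back_top <- px_to_tank(top_ctr, cams$top, tank)
  side_ctr <- bbox_center_px(boxes$side, cams$side)
  back_side <- px_to_tank(side_ctr, cams$side, tank)
  ext_top <- px_extent(cams$top, tank)
  ext_side <- px_extent(cams$side, tank)
  expect_lt(max(abs(back_top$a_cm - pts$x_cm)), ext_top[["u"]])
  expect_lt(max(abs(back_top$b_cm - pts$y_cm)), ext_top[["v"]])
  expect_lt(max(abs(back_side$b_cm - pts$z_cm)), ext_side[["v"]])
  # a tank-center point projects to the roi center in both views
  ctr <- trajectory(data.frame(frame_index = 0, timestamp_s = 0,
                               x_cm = tank$length_x_cm / 2,
                               y_cm = tank$width_y_cm / 2,
                               z_cm = tank$height_z_cm / 2))
  cb <- project_to_views(ctr, cams, tank)
  r <- cams$top$roi
  expect_equal(cb$top$cx * 1920, mean(r[c(1, 3)]))
  expect_equal(cb$top$cy * 1080, mean(r[c(2, 4)]))
})

test_that("the clean limit of corruption reproduces the truth boxes", {
  cfg <- sim_config(seed = 82, n_frames = 200, dropout_p_top = 0,
                    dropout_p_side = 0, noise_px_sd = 0, reflection_p = 0)
  tr <- simulate_trajectory(cfg, tank)
  boxes <- project_to_views(tr, cams, tank, cfg$fish_size_cm)
  stream <- corrupt_stream(boxes$top, cfg, "top", cams$top, tank)
  expect_equal(nrow(stream), 200)
  expect_equal(stream$cx, boxes$top$cx)
  expect_equal(stream$cy, boxes$top$cy)
  # confidences still drawn from the detector model, but all detections kept
  expect_true(all(stream$confidence > 0))
})

test_that("full dropout empties every frame but keeps the frame set", {
  cfg <- sim_config(seed = 83, n_frames = 50, dropout_p_top = 1,
                    reflection_p = 0)
  tr <- simulate_trajectory(cfg, tank)
  boxes <- project_to_views(tr, cams, tank, cfg$fish_size_cm)
  stream <- corrupt_stream(boxes$top, cfg, "top", cams$top, tank)
  expect_equal(nrow(stream), 0)
  expect_equal(frame_set(stream), 0:49)
})

test_that("near-wall reflections appear at the binomial rate", {
  # wall-hugging trajectory: every frame within the margin of the surface
  n <- 2000
  pts <- data.frame(frame_index = 0:(n - 1), timestamp_s = (0:(n - 1)) * 0.1,
                    x_cm = runif(n, 5, 38), y_cm = runif(n, 2, 6),
                    z_cm = tank$height_z_cm - 0.2)
  set.seed(84)
  truth <- trajectory(pts)
  cfg <- sim_config(seed = 85, n_frames = n, dropout_p_side = 0,
                    noise_px_sd = 0, reflection_p = 0.5, wall_margin_cm = 1.5)
  boxes <- project_to_views(truth, cams, tank, cfg$fish_size_cm)
  stream <- corrupt_stream(boxes$side, cfg, "side", cams$side, tank)
  n_fp <- nrow(stream) - n
  expect_gt(n_fp, 0)
  sigma <- sqrt(n * 0.5 * 0.5)
  expect_lt(abs(n_fp - n * 0.5), 5 * sigma)
  # reflections are mirrored above the water line (beyond the roi top edge)
  # and carry mid-range confidences
  fp_rows <- stream[stream$cy * 1080 < cams$side$roi[2], ]
  expect_equal(nrow(fp_rows), n_fp)
  expect_lt(mean(fp_rows$confidence), 0.85)
})

test_that("matched and reflection confidences separate at a 0.7 threshold", {
  cfg <- sim_config(seed = 86, n_frames = 3000, dropout_p_side = 0,
                    reflection_p = 0.5)
  n <- cfg$n_frames
  pts <- data.frame(frame_index = 0:(n - 1), timestamp_s = (0:(n - 1)) * 0.1,
                    x_cm = 20, y_cm = 4, z_cm = tank$height_z_cm - 0.2)
  boxes <- project_to_views(trajectory(pts), cams, tank, cfg$fish_size_cm)
  stream <- corrupt_stream(boxes$side, cfg, "side", cams$side, tank)
  # reflections are mirrored above the water line; real detections below it
  is_fp <- stream$cy * 1080 < cams$side$roi[2] + 5
  expect_gt(sum(is_fp), 100)
  # Beta(20,1) mass is near 1; Beta(4,2) is mid-range, so a 0.7 threshold
  # keeps almost all real detections but rejects around half the reflections
  expect_gt(mean(stream$confidence[!is_fp] >= 0.7), 0.99)
  expect_lt(mean(stream$confidence[is_fp] >= 0.7), 0.6)
})

test_that("long-run layer occupancy approaches the configured bias", {
  cfg <- sim_config(seed = 87, n_frames = 20000)
  tr <- simulate_trajectory(cfg, tank)
  occ <- layer_summary(region_histogram(tr, tank))
  target <- c(24.6, 17.7, 57.7)
  expect_true(all(abs(occ$pct - target) < 3))
})

test_that("reconstruction error grows with pixel noise and shrinks to the floor", {
  errs <- vapply(c(0, 2, 6), function(sigma) {
    cfg <- sim_config(seed = 88, n_frames = 400, dropout_p_top = 0,
                      dropout_p_side = 0, noise_px_sd = sigma,
                      reflection_p = 0)
    sim <- simulate_dataset(cfg, geo)
    series <- reconstruct_sequence(
      pair_streams(sim$top_stream, sim$side_stream), cams, tank)
    traj <- assemble_trajectory(fill_gaps(series))
    error_stats(traj, sim$truth)$mean_err_cm
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  bound <- max(px_extent(cams$top, tank), px_extent(cams$side, tank))
  expect_lt(errs[1], bound)
})
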