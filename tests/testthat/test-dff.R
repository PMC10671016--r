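test_that("background subtraction clips at zero and is identity at level 0", {
  rec <- constant_recording(100)
  expect_identical(subtract_background(rec, 0), rec)
  expect_true(all(subtract_background(rec, 40)$frames == 60))
  expect_true(all(subtract_background(rec, 150)$frames == 0))
  bad <- matrix(1, 3, 3)
  expect_error(subtract_background(rec, bad), "background image")
})

test_that("per-pixel background equal to the frames invalidates every pixel", {
  rec <- constant_recording(100, n_rows = 3, n_cols = 3)
  bg <- matrix(100, 3, 3)
  zeroed <- subtract_background(rec, bg)
  expect_true(all(zeroed$frames == 0))
  f0 <- compute_f0(zeroed, c(-5, 0))
  expect_false(any(f0$valid))
})

test_that("F0 is the per-pixel mean over the baseline window", {
  rec <- constant_recording(100)
  expect_true(all(compute_f0(rec, c(-5, 0))$f0 == 100))
  # alternating 90/110 frames
  fr <- array(rep(c(90, 110), each = 1, times = 5), dim = c(10, 1, 1))
  rec2 <- make_recording(fr, pre_min = 10, fpm = 1)
  expect_equal(as.numeric(compute_f0(rec2, c(-10, 0))$f0), 100)
  expect_error(compute_f0(rec, c(-5, 2)), "injection")
  expect_error(compute_f0(rec, c(-20, -10)), "no frames")
})

test_that("noiseless saline F0 equals the generator baseline exactly", {
  sim <- simulate_session(simulation_params(
    geometry = sensor_geometry(6, 9),
    kinetics = kinetic_profile("saline", artifact_depth = 0),
    read_noise_sd = 0, shot_noise_gain = 0, pre_min = 5, post_min = 20,
    sim_fps = 0.1, seed = 3))
  f0 <- compute_f0(sim$recording, c(-5, 0))
  expect_equal(f0$f0, sim$truth$baseline)
})

test_that("dF/F0 follows (F - F0) / F0 * 100", {
  rec <- constant_recording(100, n_frames = 3)
  f0 <- compute_f0(rec, c(-5, -2))
  expect_true(all(compute_dff(rec, f0)$values == 0))
  rec$frames[] <- 200
  expect_true(all(compute_dff(rec, f0)$values == 100))
  rec$frames[] <- 110
  expect_true(all(compute_dff(rec, f0)$values == 10))
  expect_error(compute_dff(constant_recording(1, n_rows = 2, n_cols = 2),
                           f0), "dimensions")
})

test_that("dF/F0 is invariant under a global gain", {
  s <- quick_session(seed = 4, post_min = 20, sim_fps = 0.05,
                     geometry = sensor_geometry(8, 10))
  rec <- s$sim$recording
  for (c_gain in c(0.25, 3.7)) {
    rec2 <- rec
    rec2$frames <- rec$frames * c_gain
    dff2 <- compute_dff(rec2, compute_f0(rec2))
    expect_equal(dff2$values, s$dff$values, tolerance = 1e-12)
  }
})

test_that("interval averaging follows the end-labelled binning rule", {
  # constant stack: every interval equals the constant
  dffc <- make_dff(array(7, dim = c(20, 2, 2)),
                   -5 + (1:20 - 0.5) * 1)
  tr <- average_intervals(dffc, 5, mode = "trace")
  expect_true(all(tr$values == 7))
  # dff(t) = t on frames at t = 1..10 min, width 5 -> means 3 and 8
  vals <- array(rep(1:10, 4), dim = c(10, 2, 2))
  dfft <- make_dff(vals, 1:10 - 0.5 + 0.5)  # centres at 1..10, dt = 1
  tr2 <- average_intervals(dfft, 5, mode = "trace")
  expect_equal(tr2$labels, c(5, 10))
  expect_equal(unname(tr2$values), c(3, 8))
  # 17 min of frames at width 5 -> exactly 3 complete intervals
  vals3 <- array(1, dim = c(17, 2, 2))
  dff3 <- make_dff(vals3, (1:17) - 0.5)
  expect_equal(length(average_intervals(dff3, 5, "trace")$labels), 3)
  expect_error(average_intervals(dff3, 100, "trace"), "span")
})

test_that("whole-image trace averages valid pixels per frame", {
  vals <- array(0, dim = c(4, 2, 2))
  vals[, 1, ] <- 10  # half the pixels at 10, half at 0
  dff <- make_dff(vals, 1:4)
  expect_equal(whole_image_trace(dff), rep(5, 4))
  dffu <- make_dff(array(3.5, dim = c(4, 2, 2)), 1:4)
  expect_equal(whole_image_trace(dffu), rep(3.5, 4))
  dffn <- make_dff(vals, 1:4, valid = matrix(FALSE, 2, 2))
  expect_error(whole_image_trace(dffn), "valid")
})

test_that("pixel and time averaging commute on fully valid stacks", {
  set.seed(21)
  vals <- array(rnorm(30 * 4 * 5), dim = c(30, 4, 5))
  dff <- make_dff(vals, -5 + (1:30 - 0.5))
  imgs <- average_intervals(dff, 5, "images")
  tr <- average_intervals(dff, 5, "trace")
  expect_equal(apply(imgs$images, 1, mean), unname(tr$values))
})

test_that("noiseless sessions recover the planted kinetic curve", {
  # the handling dip is part of the planted curve and recovered with it
  sim <- simulate_session(simulation_params(
    read_noise_sd = 0, shot_noise_gain = 0, pre_min = 15, post_min = 60,
    sim_fps = 0.05, seed = 5))
  dff <- compute_dff(sim$recording, compute_f0(sim$recording))
  tr <- whole_image_trace(dff)
  truth <- sim$truth$kinetic_curve
  expect_gt(stats::cor(tr, truth), 1 - 1e-9)
  # least-squares scale leaves < 1e-6 residual
  sc <- sum(tr * truth) / sum(truth^2)
  expect_lt(max(abs(tr - sc * truth)), 1e-6)
  expect_gt(sc, 0)
})

test_that("single noiseless site reproduces coupling * kinetic at its centre", {
  bg <- 0.3
  p <- simulation_params(
    kinetics = kinetic_profile("morphine_like", artifact_depth = 0),
    n_sites = 1, site_gain_range = c(1, 1), read_noise_sd = 0,
    shot_noise_gain = 0, background_coupling = bg, pre_min = 15,
    post_min = 60, sim_fps = 0.05, seed = 9)
  sim <- simulate_session(p)
  dff <- compute_dff(sim$recording, compute_f0(sim$recording))
  s <- sim$truth$sites[[1]]
  r <- round(s$center_row); cc <- round(s$center_col)
  coup <- sim$truth$coupling[r, cc]
  expect_equal(dff$values[, r, cc],
               100 * coup * sim$truth$kinetic_curve, tolerance = 1e-9)
  # at the sampled peak the site centre sits near amplitude * (gain + bg)
  pk <- which.max(sim$truth$kinetic_curve)
  expect_equal(dff$values[pk, r, cc],
               100 * coup * max(sim$truth$kinetic_curve), tolerance = 1e-9)
})
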