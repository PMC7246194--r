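test_that("running mean is a centered box filter with shrinking edges", {
  expect_equal(running_mean(rep(3.5, 50), 2, 40), rep(3.5, 50))
  x <- c(rep(0, 10), 1, rep(0, 10))
  y <- running_mean(x, 5 / 40, 40)  # 5-sample window
  expect_equal(y[9:13], rep(0.2, 5))
  expect_equal(y[c(8, 14)], c(0, 0))
  # even sample count is forced odd: window of 4 samples behaves as 5
  expect_equal(running_mean(x, 4 / 40, 40), y)
  # edges shrink: first value averages the first 1 + h samples
  z <- running_mean(1:10, 5 / 40, 40)
  expect_equal(z[1], mean(1:3))
  expect_equal(z[10], mean(8:10))
  expect_identical(running_mean(numeric(0), 2, 40), numeric(0))
  expect_error(running_mean(1:10, 0.001, 40), class = "hods_parameter_error")
})

test_that("running mean shrinks white-noise variance as 1/n", {
  sds <- vapply(1:10, function(seed) {
    set.seed(300 + seed)
    sd(running_mean(rnorm(4000), 2, 40)[100:3900])
  }, numeric(1))
  expect_lt(abs(mean(sds) - 1 / sqrt(81)), 0.2 / sqrt(81))
})

test_that("pitch formula reproduces closed-form angles", {
  expect_equal(pitch_from_acc(1, 0, 0), 90)
  expect_equal(pitch_from_acc(0, 1, 0), 0)
  expect_equal(pitch_from_acc(0.5, 0.8660254, 0), 30, tolerance = 1e-7)
  expect_equal(pitch_from_acc(-1, 0, 0), -90)
  expect_error(pitch_from_acc(0, 0, 0), class = "hods_undefined_orientation")
})

test_that("roll formula follows the right-side-down convention", {
  expect_equal(roll_from_acc(1, 0), 0)
  expect_equal(roll_from_acc(0, 1), 90)
  expect_equal(roll_from_acc(-1, 0), 180)
  expect_equal(roll_from_acc(0, -1), -90)
  expect_error(roll_from_acc(0, 0), class = "hods_undefined_roll")
})

test_that("pitch sensitivity decreases monotonically away from the horizontal", {
  # |d pitch / d surge| at fixed lateral axes, evaluated numerically
  pitches <- seq(0, 85, by = 5)
  eps <- 1e-6
  deriv <- vapply(pitches, function(p) {
    s <- sin(p * pi / 180)
    c_ <- sqrt(1 - s^2)
    abs(pitch_from_acc(s + eps, c_, 0) - pitch_from_acc(s, c_, 0)) / eps
  }, numeric(1))
  expect_true(all(diff(deriv) < 0))
})

test_that("tilt-compensated heading matches the stated conventions", {
  expect_equal(tilt_compensated_heading(0, 0, c(1, 0, 0.5)), 0)
  expect_equal(tilt_compensated_heading(0, 0, c(0, -1, 0.5)), 90)
  # pitched 30 deg facing 220 under a 60-deg-inclination field, sensor-frame
  # mag computed by the simulator forward model
  tr <- orientation_series(heading = rep(220, 4), pitch = rep(30, 4), fs = 40)
  imu <- synthesize_imu(tr, world_model(inclination_deg = 60))
  h <- tilt_compensated_heading(rep(30, 4), rep(0, 4),
                                cbind(imu$mag_x, imu$mag_y, imu$mag_z))
  expect_equal(h, rep(220, 4), tolerance = 1e-6)
  expect_error(tilt_compensated_heading(0, 0, c(0, 0, 0)),
               class = "hods_undefined_orientation")
})

test_that("derive_orientation recovers a static level tag exactly", {
  n <- 200
  imu <- imu_series(acc_surge = rep(0, n), acc_heave = rep(1, n),
                    acc_sway = rep(0, n), mag_x = rep(cos(pi / 3), n),
                    mag_y = rep(0, n), mag_z = rep(-sin(pi / 3), n), fs = 40)
  o <- derive_orientation(imu)
  expect_true(all(o$valid))
  expect_equal(o$heading, rep(0, n))
  expect_equal(o$pitch, rep(0, n))
  expect_equal(o$roll, rep(0, n))
})

test_that("a dynamic-acceleration burst is flagged invalid by the 1-g check", {
  n <- 400  # 10 s at 40 Hz
  heave <- rep(1, n)
  burst <- 161:240  # 2-s burst of 2-g total acceleration
  heave[burst] <- 2
  imu <- imu_series(acc_surge = rep(0, n), acc_heave = heave,
                    acc_sway = rep(0, n), mag_x = rep(0.5, n),
                    mag_y = rep(0, n), mag_z = rep(-0.866, n), fs = 40)
  o <- derive_orientation(imu)
  expect_true(all(!o$valid[181:220]))   # core of the burst
  expect_true(all(o$valid[1:100]))
  expect_true(all(is.nan(o$heading[!o$valid])))
})

test_that("the gimbal guard invalidates near-vertical pitch", {
  n <- 100
  imu <- imu_series(acc_surge = rep(1, n), acc_heave = rep(0.01, n),
                    acc_sway = rep(0, n), mag_x = rep(0.5, n),
                    mag_y = rep(0.1, n), mag_z = rep(-0.86, n), fs = 40)
  o <- derive_orientation(imu)
  expect_true(all(!o$valid))
})

test_that("simulated orientation is recovered within stated error at tag noise", {
  bo <- build_orientation(behavior_script(
    list(seg_fixation(4, 80, -20), seg_scan(6, 10, "yaw"),
         seg_turn(300, -20), seg_fixation(4)), fs = 40, start_pitch = -20))
  w <- world_model(noise_acc = 0.005, noise_mag = 0.005)
  imu <- synthesize_imu(bo$truth, w, seed = 42)
  o <- derive_orientation(imu)
  v <- o$valid & bo$truth$valid
  h_rmse <- sqrt(mean(wrap180(o$heading[v] - bo$truth$heading[v])^2))
  p_rmse <- sqrt(mean((o$pitch[v] - bo$truth$pitch[v])^2))
  expect_lt(h_rmse, 2)
  expect_lt(p_rmse, 1)
})

test_that("heading recovery is equivariant under a world-frame rotation", {
  base <- behavior_script(list(seg_fixation(3, 40, 10),
                               seg_scan(3, 8, "yaw")), fs = 40,
                          start_pitch = 10)
  bo <- build_orientation(base)
  o1 <- derive_orientation(synthesize_imu(bo$truth, world_model()))
  for (delta in c(30, 123.4, 270)) {
    shifted <- bo$truth
    shifted$heading <- wrap360(shifted$heading + delta)
    o2 <- derive_orientation(synthesize_imu(shifted, world_model()))
    expect_equal(wrap360(o2$heading - o1$heading),
                 rep(wrap360(delta), length(o1$heading)), tolerance = 1e-9)
  }
})

test_that("angle ranges hold over random inputs", {
  set.seed(310)
  for (k in 1:20) {
    tr <- orientation_series(heading = runif(50, 0, 360),
                             pitch = runif(50, -60, 60),
                             roll = runif(50, -179, 180), fs = 40)
    o <- derive_orientation(synthesize_imu(tr, world_model()),
                            params = orientation_params(smooth_window = 1 / 40))
    v <- o$valid
    expect_true(all(o$heading[v] >= 0 & o$heading[v] < 360))
    expect_true(all(o$pitch[v] >= -90 & o$pitch[v] <= 90))
    expect_true(all(o$roll[v] > -180 & o$roll[v] <= 180 + 1e-12))
  }
})

test_that("noise-free round trip including roll is exact with minimal smoothing", {
  set.seed(311)
  tr <- orientation_series(heading = runif(100, 0, 360),
                           pitch = runif(100, -80, 80),
                           roll = runif(100, -170, 170), fs = 40)
  o <- derive_orientation(synthesize_imu(tr, world_model()),
                          params = orientation_params(smooth_window = 1 / 40))
  v <- o$valid
  expect_gt(mean(v), 0.9)
  expect_lt(max(abs(wrap180(o$heading[v] - tr$heading[v]))), 1e-6)
  expect_lt(max(abs(o$pitch[v] - tr$pitch[v])), 1e-6)
  expect_lt(max(abs(wrap180(o$roll[v] - tr$roll[v]))), 1e-6)
})
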