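test_that("SSSD is zero for constant orientation and matches the antipodal closed form", {
  tr <- sssd(rep(123, 100), rep(-7, 100), 10)
  expect_equal(tr$s, rep(0, length(tr$s)))
  expect_equal(tr$index, 6:95)

  for (W in c(4, 10, 40)) {
    h <- c(rep(0, W / 2 + 1), rep(180, W / 2))
    tr2 <- sssd(h, rep(0, W + 1), W)
    expect_length(tr2$s, 1L)
    expect_equal(tr2$s, 2 * log(W + 1), tolerance = 1e-12)
  }

  expect_error(sssd(rep(0, 50), rep(0, 50), 7), "even",
               class = "hods_parameter_error")
  expect_error(sssd(rep(0, 10), rep(0, 10), 10), class = "hods_parameter_error")
})

test_that("vectorized SSSD equals the brute-force oracle on random series", {
  set.seed(600)
  for (k in 1:5) {
    h <- runif(300, 0, 360)
    p <- runif(300, -90, 90)
    for (W in c(4, 10, 40)) {
      got <- sssd(h, p, W)
      want <- brute_sssd(h, p, W)
      expect_identical(got$index, as.integer(want$index))
      expect_lt(max(abs(got$s - want$s)), 1e-12)
    }
  }
})

test_that("SSSD reduces to the squared circular standard deviation at zero pitch", {
  set.seed(601)
  h <- runif(200, 0, 360)
  W <- 20
  tr <- sssd(h, rep(0, 200), W)
  for (k in seq_along(tr$index)) {
    w <- (tr$index[k] - W / 2):(tr$index[k] + W / 2)
    expect_lt(abs(tr$s[k] - circular_sq_sd(h[w])), 1e-12)
  }
})

test_that("SSSD is invariant under rigid rotations of the orientation set", {
  set.seed(602)
  h <- runif(200, 0, 360)
  p <- runif(200, -80, 80)
  base <- sssd(h, p, 12)$s
  xyz <- to_sphere(h, p)
  for (k in 1:10) {
    R <- random_rotation()
    ang <- sphere_to_angles(xyz %*% t(R))
    expect_lt(max(abs(sssd(ang$heading, ang$pitch, 12)$s - base)), 1e-9)
  }
})

test_that("windows containing invalid samples are undefined and split spikes", {
  h <- c(rep(0, 30), NaN, rep(0, 30))
  tr <- sssd(h, rep(0, 61), 10)
  expect_false(any(tr$index %in% 26:36))
  expect_true(all(is.finite(tr$s)))
})

test_that("spikes are strict supra-mean runs", {
  expect_equal(nrow(find_spikes(sssd_trace(rep(0, 7)))), 0L)

  tr <- sssd_trace(c(0, 0, 5, 6, 5, 0, 0))
  expect_equal(tr$global_mean, 16 / 7)
  sp <- find_spikes(tr)
  expect_equal(sp$start, 3L)
  expect_equal(sp$end, 5L)
  expect_equal(spike_midpoint(sp$start, sp$end), 4L)

  two <- find_spikes(sssd_trace(c(0, 4, 0, 0, 5, 5, 0)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(2L, 5L))
  expect_equal(two$end, c(2L, 6L))
})

test_that("spike midpoints use the floor tie-break", {
  expect_equal(spike_midpoint(10L, 14L), 12L)
  expect_equal(spike_midpoint(10L, 13L), 11L)
  expect_equal(spike_midpoint(7L, 7L), 7L)
  expect_error(spike_midpoint(5L, 4L), class = "hods_parameter_error")
})

test_that("turn angle measures the before/after reorientation", {
  const <- orientation_series(heading = rep(10, 100), pitch = rep(0, 100),
                              fs = 40)
  expect_equal(turn_angle(const, 50, 40), 0)

  s <- orientation_series(heading = c(rep(0, 50), rep(90, 50)),
                          pitch = rep(0, 100), fs = 40)
  expect_equal(turn_angle(s, 50, 40), 90, tolerance = 1e-9)
  expect_error(turn_angle(s, 5, 40), class = "hods_parameter_error")

  # scripted 45-deg turn with noisy headings: unbiased within 2 deg
  set.seed(603)
  est <- vapply(1:50, function(k) {
    h <- c(rep(0, 50), rep(45, 50)) + rnorm(100, 0, 2)
    turn_angle(orientation_series(heading = wrap360(h),
                                  pitch = rep(0, 100), fs = 40), 50, 40)
  }, numeric(1))
  expect_lt(abs(mean(est) - 45), 2)
})

test_that("detection finds a scripted turn and rejects sub-threshold ones", {
  const <- orientation_series(heading = rep(42, 500), pitch = rep(3, 500),
                              fs = 40)
  expect_equal(nrow(detect_turning_points(const)$accepted), 0L)

  sc <- behavior_script(list(seg_fixation(5, 0, 0), seg_turn(90, 0),
                             seg_fixation(5)), fs = 40)
  bo <- build_orientation(sc)
  tp <- detect_turning_points(bo$truth, W = 40, theta_thresh = 30)
  expect_equal(nrow(tp$accepted), 1L)
  expect_lte(abs(tp$accepted$index - bo$turns), 20)
  expect_equal(tp$accepted$turn_angle, 90, tolerance = 1e-9)

  sc2 <- behavior_script(list(seg_fixation(5, 0, 0), seg_turn(20, 0),
                              seg_fixation(5)), fs = 40)
  tp2 <- detect_turning_points(build_orientation(sc2)$truth, 40, 30)
  expect_gte(length(tp2$candidates), 1L)
  expect_equal(nrow(tp2$accepted), 0L)
})

test_that("detection is translation-equivariant in time", {
  mk <- function(lead) {
    sc <- behavior_script(list(seg_fixation(lead, 10, 0), seg_turn(120, 10),
                               seg_fixation(6)), fs = 40)
    detect_turning_points(build_orientation(sc)$truth)$accepted$index - 1
  }
  base <- mk(6)
  shift <- mk(8)
  expect_equal(shift - base, 2 * 40)
})

test_that("seeded noisy scripts are recovered with high sensitivity and few false alarms", {
  set.seed(604)
  n_scripts <- 25
  hits <- 0; total <- 0; false_pos <- 0
  for (r in seq_len(n_scripts)) {
    bo <- build_orientation(turn_script(sample(1:5, 1)))
    n <- length(bo$truth$t)
    noisy <- orientation_series(
      heading = wrap360(bo$truth$heading + rnorm(n, 0, 2)),
      pitch = bo$truth$pitch, fs = 40)
    det <- detect_turning_points(noisy, 40, 30)$accepted$index
    hits <- hits + sum(vapply(bo$turns, function(ti)
      any(abs(det - ti) <= 20), logical(1)))
    total <- total + length(bo$turns)
    false_pos <- false_pos + sum(vapply(det, function(d)
      !any(abs(bo$turns - d) <= 20), logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_lte(false_pos / n_scripts, 0.05)
})

test_that("turning-point JSON export lists spikes, candidates and acceptances", {
  sc <- behavior_script(list(seg_fixation(5, 0, 0), seg_turn(90, 0),
                             seg_fixation(5)), fs = 40)
  tp <- detect_turning_points(build_orientation(sc)$truth)
  f <- withr::local_tempfile(fileext = ".json")
  write_turning_points(tp, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$W, 40)
  expect_equal(j$accepted$index, tp$accepted$index)
  expect_equal(length(j$trace$s), length(tp$trace$s))
})
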