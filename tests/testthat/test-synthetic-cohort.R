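test_that("synthetic pen traces follow an Archimedes spiral at constant rate", {
  pen <- synth_spiral_pen(10, n_turns = 3, fs_pen = 100, lead_pen_up = 1, seed = 1)
  expect_equal(sum(pen$pressure > 0), 1000)
  expect_equal(pen$pressure[1:100], rep(0, 100))
  expect_equal(segment_task(pen)$pen_down_duration, 10, tolerance = 1 / 100)

  # unwrapped polar angle of the pen-down samples spans n_turns * 2*pi
  down <- pen[pen$pressure > 0, ]
  th <- atan2(down$y, down$x)[-1]  # centre point has undefined angle
  unw <- th + 2 * pi * cumsum(c(0, diff(th) < -pi)) - 2 * pi * cumsum(c(0, diff(th) > pi))
  expect_equal((max(unw) - min(unw)) / (6 * pi), 1, tolerance = 0.01)

  # radius grows linearly with angle (r = a * theta)
  r <- sqrt(down$x^2 + down$y^2)
  expect_gt(cor(r, seq_along(r)), 0.9999)

  expect_error(synth_spiral_pen(-1), class = "invalid_parameter")
  expect_error(synth_spiral_pen(10, n_turns = 0), class = "invalid_parameter")
  expect_error(synth_spiral_pen(10, fs_pen = -5), class = "invalid_parameter")
})

test_that("synthetic accelerometer traces compose tremor, voluntary drive and noise", {
  pen <- synth_spiral_pen(10, seed = 2)

  # no tremor, no noise: essentially no power in the tremor band
  quiet <- synth_accel(pen, tremor_spec(6, 0, noise_sd = 0), seed = 3)
  f <- extract_features(quiet, pen)
  expect_lt(f$psd_ratio, 0.05)

  # doubling the tremor amplitude quadruples the PSD ratio
  r1 <- extract_features(synth_accel(pen, tremor_spec(6, 0.1, noise_sd = 0), seed = 3), pen)$psd_ratio
  r2 <- extract_features(synth_accel(pen, tremor_spec(6, 0.2, noise_sd = 0), seed = 3), pen)$psd_ratio
  expect_equal(r2 / r1, 4, tolerance = 0.1)

  # seeded regeneration is bit-identical
  a1 <- synth_accel(pen, tremor_spec(7, 0.1), seed = 9)
  a2 <- synth_accel(pen, tremor_spec(7, 0.1), seed = 9)
  expect_identical(a1, a2)

  # gravity sits on one axis before filtering
  expect_gt(mean(quiet$az), 9)
  expect_lt(abs(mean(quiet$ax)), 1)

  expect_error(synth_accel(pen, tremor_spec(8, 0.1), fs = 15), class = "aliasing_error")
})

test_that("amplitude calibration inverts the band-power ratio", {
  vol <- msig(2, 1, dur = 20)
  expect_equal(calibrate_amplitude(0, vol), 0)
  expect_equal(calibrate_amplitude(4, vol, tremor_freq = 6), 2, tolerance = 0.03)

  silent <- magnitude_signal(vol$t, rep(0, length(vol$m)), vol$fs, filtered = TRUE)
  expect_error(calibrate_amplitude(4, silent), class = "division_by_zero")
  expect_error(calibrate_amplitude(-1, vol), class = "invalid_parameter")
  expect_error(calibrate_amplitude(4, vol, tremor_freq = 2), class = "invalid_parameter")

  # round trip: synthesise with the calibrated amplitude, extract the ratio
  pen <- synth_spiral_pen(12, seed = 5)
  w <- segment_task(pen)
  volacc <- synth_accel(pen, tremor_spec(7.2, 0, noise_sd = 0), seed = 6)
  mag <- highpass(vector_magnitude(slice_accel(volacc, w)))
  target <- 4
  a <- calibrate_amplitude(target, mag, 7.2)
  geom <- spiraltremor:::.synth_geometry()
  full <- synth_accel(pen, tremor_spec(7.2, a / (geom$tremor_dir[3] * sqrt(1 + 0.2^2 / 2)),
                                       noise_sd = 0.01), seed = 6)
  expect_equal(extract_features(full, pen)$psd_ratio, target, tolerance = 0.1)
})

test_that("cohort generation hits the configured group structure deterministically", {
  coh <- make_cohort(small_group_params(), seed = 21)
  groups <- vapply(coh$subjects, function(s) s$group_label, "")
  expect_equal(as.integer(table(groups)[c("control", "ET0", "ET1plus", "ET2plus")]),
               c(3L, 3L, 2L, 2L))

  # regeneration is identical; written CSVs are byte-identical
  coh2 <- make_cohort(small_group_params(), seed = 21)
  expect_identical(coh, coh2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(coh, d1); write_cohort(coh2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # clinical consistency: controls unscored, ET scores in [0, 144]
  clin <- read_cohort_csv(file.path(d1, "cohort.csv"))
  expect_true(all(is.na(clin$ftm_rater1[clin$group == "control"])))
  et <- clin[clin$group != "control", ]
  expect_true(all(et$ftm_rater1 >= 0 & et$ftm_rater1 <= 144))
  expect_equal(clin$ftm_mean, (clin$ftm_rater1 + clin$ftm_rater2) / 2)

  # every accel trace shares the pen's task window
  sub <- coh$subjects[[1]]
  for (site in c("S1", "S2", "S3")) {
    expect_equal(range(sub$accel[[site]]$t), range(sub$pen$t), tolerance = 1 / 100)
  }
})

test_that("degenerate group SDs give identical per-subject targets", {
  p <- list(group_params("ET0", 4, c(2, 3, 1), c(0, 0, 0), 12, 0, mean_ftm = 15, sd_ftm = 0))
  coh <- make_cohort(p, seed = 3, noise_sd = 0)
  tg <- t(vapply(coh$subjects, function(s) s$targets$psd_ratio, numeric(3)))
  expect_true(all(apply(tg, 2, function(v) diff(range(v)) == 0)))
  tt <- vapply(coh$subjects, function(s) s$targets$task_time, 0)
  expect_equal(diff(range(tt)), 0)
  # extracted ratios agree across subjects up to spectral-estimation noise
  f <- cohort_features(coh, sites = "S2")
  expect_lt(diff(range(f$psd_ratio)) / mean(f$psd_ratio), 0.15)
})

test_that("raising a group's configured mean ratio raises its extracted mean", {
  base <- list(group_params("ET0", 6, c(2, 2, 2), c(0.5, 0.5, 0.5), 12, 2))
  up <- list(group_params("ET0", 6, c(2, 4, 2), c(0.5, 0.5, 0.5), 12, 2))
  f_base <- cohort_features(make_cohort(base, seed = 31), sites = "S2")
  f_up <- cohort_features(make_cohort(up, seed = 31), sites = "S2")
  expect_gt(mean(f_up$psd_ratio), mean(f_base$psd_ratio))
})

test_that("generator parameter validation rejects impossible settings", {
  expect_error(group_params("control", 0, rep(1, 3), rep(0, 3), 10, 1),
               class = "invalid_parameter")
  expect_error(group_params("control", 3, rep(-1, 3), rep(0, 3), 10, 1),
               class = "invalid_parameter")
  expect_error(group_params("control", 3, rep(1, 2), rep(0, 2), 10, 1),
               class = "invalid_parameter")
  expect_error(tremor_spec(tremor_freq = 3), class = "invalid_parameter")
  expect_error(tremor_spec(tremor_amplitude = -1), class = "invalid_parameter")
  expect_error(tremor_spec(am_depth = 1.2), class = "invalid_parameter")
  expect_error(make_cohort(list()), class = "invalid_parameter")
})
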