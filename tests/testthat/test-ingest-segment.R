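test_that("accelerometer CSV reading is header-keyed and validates its input", {
  dir <- withr::local_tempdir()
  t <- (0:3) / 148.1
  df <- data.frame(t = t, ax = c(1, 2, 3, 4), ay = 0, az = 9.81)
  p1 <- file.path(dir, "a.csv")
  utils::write.csv(df, p1, row.names = FALSE)
  tr <- read_accel_csv(p1, site = "S1")
  expect_s3_class(tr, "accel_trace")
  expect_equal(attr(tr, "fs"), 148.1, tolerance = 1e-6)
  expect_equal(attr(tr, "site"), "S1")

  # reordered columns give the identical trace
  p2 <- file.path(dir, "b.csv")
  utils::write.csv(df[, c("az", "t", "ay", "ax")], p2, row.names = FALSE)
  expect_identical(as.data.frame(read_accel_csv(p2, "S1")), as.data.frame(tr))

  # schema errors
  p3 <- file.path(dir, "empty.csv")
  writeLines("", p3)
  expect_error(read_accel_csv(p3), class = "schema_error")
  p4 <- file.path(dir, "missing.csv")
  utils::write.csv(df[, c("t", "ax", "ay")], p4, row.names = FALSE)
  expect_error(read_accel_csv(p4), class = "schema_error")
  expect_error(read_accel_csv(file.path(dir, "nope.csv")), class = "schema_error")

  # non-monotone time is a data error
  p5 <- file.path(dir, "nonmono.csv")
  utils::write.csv(transform(df, t = c(0, 2, 1, 3)), p5, row.names = FALSE)
  expect_error(read_accel_csv(p5), class = "data_error")

  # off-nominal sampling rate is flagged but used
  p6 <- file.path(dir, "slow.csv")
  utils::write.csv(transform(df, t = (0:3) / 100), p6, row.names = FALSE)
  expect_warning(tr6 <- read_accel_csv(p6), "deviates")
  expect_equal(attr(tr6, "fs"), 100, tolerance = 1e-6)
})

test_that("pen CSV reading validates pressure and round-trips through write", {
  dir <- withr::local_tempdir()
  pen <- synth_spiral_pen(3, n_turns = 2, fs_pen = 50, lead_pen_up = 0.5, seed = 4)
  path <- file.path(dir, "pen.csv")
  write_trace_csv(pen, path)
  back <- read_pen_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(pen), tolerance = 1e-12)
  expect_equal(attr(back, "fs"), attr(pen, "fs"), tolerance = 1e-9)

  ok <- data.frame(t = (0:5) / 10, x = 1:6, y = 1:6, pressure = 1)
  p2 <- file.path(dir, "alldown.csv")
  utils::write.csv(ok, p2, row.names = FALSE)
  tr <- read_pen_csv(p2)
  expect_equal(sum(tr$pressure == 0), 0)

  bad <- transform(ok, pressure = c(1, 1, -0.1, 1, 1, 1))
  p3 <- file.path(dir, "neg.csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(read_pen_csv(p3), class = "data_error")
})

test_that("stroke labelling partitions the trace into maximal runs", {
  mk <- function(pressure) {
    z <- rep(0, length(pressure))
    pen_trace(seq_along(pressure) / 10, z, z, pressure, fs = 10)
  }

  s <- label_strokes(mk(c(0, 0, 1, 1, 0, 1)))
  expect_equal(s$kind, c("pen_up", "pen_down", "pen_up", "pen_down"))
  expect_equal(s$start, c(1, 3, 5, 6))
  expect_equal(s$end, c(2, 4, 5, 6))

  expect_equal(label_strokes(mk(c(0, 0, 0)))$kind, "pen_up")
  expect_equal(nrow(label_strokes(mk(rep(c(0, 1), 10)))), 20)

  # partition property on random pressure traces, against a hand loop counter
  set.seed(11)
  for (i in 1:20) {
    p <- sample(c(0, 0, 1), 30, replace = TRUE)
    s <- label_strokes(mk(p))
    expect_equal(sum(s$n), 30)
    expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1))
    runs <- 1 + sum((p[-1] > 0) != (p[-30] > 0))
    expect_equal(nrow(s), runs)
  }

  # chatter filter merges sub-threshold strokes
  chat <- mk(c(1, 1, 1, 0, 1, 1, 1))
  expect_equal(nrow(label_strokes(chat)), 3)
  expect_equal(nrow(label_strokes(chat, min_duration = 0.15)), 1)
})

test_that("task segmentation counts pen-down samples only", {
  mk <- function(pressure, fs = 10) {
    z <- rep(0, length(pressure))
    pen_trace(seq_along(pressure) / fs, z, z, pressure, fs = fs)
  }

  w <- segment_task(mk(c(0, 1, 1, 1, 0)))
  expect_equal(w$pen_down_duration, 0.3)
  expect_equal(w$t_start, 0.2)
  expect_equal(w$t_end, 0.4)

  # pen-up gap inside the task is excluded from T but inside the window
  w2 <- segment_task(mk(c(0, 1, 1, 0, 1, 1, 0)))
  expect_equal(w2$pen_down_duration, 0.4)
  expect_equal(w2$t_start, 0.2)
  expect_equal(w2$t_end, 0.6)

  expect_error(segment_task(mk(c(0, 0, 0))), class = "no_pen_down")

  # against a synthetic pen trace: T recovers the drawing duration
  for (d in c(5, 12.34)) {
    pen <- synth_spiral_pen(d, fs_pen = 100, seed = 1)
    expect_equal(segment_task(pen)$pen_down_duration, d, tolerance = 1 / 100 + 1e-9)
  }
})

test_that("task-window slicing uses a closed interval and is idempotent", {
  t <- seq(0, 10, by = 0.01)
  acc <- accel_trace(t, sin(t), cos(t), t, site = "S2", fs = 100)
  mkw <- function(t0, t1) structure(list(t_start = t0, t_end = t1,
                                         pen_down_duration = t1 - t0,
                                         n_pen_down = 1L), class = "task_window")

  expect_equal(nrow(slice_accel(acc, mkw(0, 10))), nrow(acc))

  inner <- slice_accel(acc, mkw(2.005, 7.005))
  expect_true(all(inner$t >= 2.005 & inner$t <= 7.005))
  expect_equal(min(inner$t), 2.01)   # boundary samples in iff t in [t0, t1]
  expect_equal(max(inner$t), 7.00)

  twice <- slice_accel(inner, mkw(2.005, 7.005))
  expect_identical(as.data.frame(twice), as.data.frame(inner))

  expect_error(slice_accel(acc, mkw(20, 30)), class = "alignment_error")
  expect_error(slice_accel(acc, mkw(1, 1.5)), class = "too_short")

  # clock offset shifts the window onto the accelerometer clock
  shifted <- slice_accel(acc, mkw(1, 6), clock_offset = 2)
  expect_equal(range(shifted$t), c(3, 8))
})

test_that("timestamp gaps beyond three sample periods are flagged", {
  t <- c(seq(0, 1, by = 0.01), 1.2, seq(1.21, 2, by = 0.01))
  z <- rep(0, length(t))
  expect_warning(tr <- accel_trace(t, z, z, seq_along(t), fs = 100), "gap")
  expect_length(attr(tr, "gaps_flagged"), 1)
})
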