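# Synthetic spiral-drawing cohort generator.
#
# Signal model per subject and sensor site:
#   accel(t) = voluntary drawing component (second difference of the pen
#              trajectory, energy below ~3.5 Hz, mapped into the sensor frame)
#            + low-frequency corrective "wobble" (sum of tones in ~1-3.3 Hz,
#              the voluntary band content that real drawing always contains)
#            + amplitude-modulated tremor sinusoid in the 4-12 Hz band
#            + white sensor noise
#            + constant gravity on one axis.
# The tremor amplitude is calibrated per site so the extracted PSD ratio hits
# a target drawn from the configured group distribution.

#' Per-group generator parameters
#'
#' Defines one subject group for the synthetic cohort: its size and the
#' mean/SD of the per-site PSD-ratio targets, the task time, and (for ET
#' groups) the clinical FTM score.
#'
#' @param group_label One of `"control"`, `"ET0"`, `"ET1plus"`, `"ET2plus"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param mean_ratio,sd_ratio Length-3 numeric: PSD-ratio target mean and SD
#'   at sites S1, S2, S3 (means >= 0, SDs >= 0).
#' @param mean_task_time,sd_task_time Task-time distribution in seconds.
#' @param mean_ftm,sd_ftm Clinical FTM distribution (NA for controls).
#' @return A list of class `"group_params"`.
#' @export
group_params <- function(group_label, n_subjects, mean_ratio, sd_ratio,
                         mean_task_time, sd_task_time,
                         mean_ftm = NA_real_, sd_ftm = NA_real_) {
  group_label <- match.arg(group_label, c("control", "ET0", "ET1plus", "ET2plus"))
  if (!is_count(n_subjects)) stop_st("invalid_parameter", "n_subjects must be a positive integer")
  if (length(mean_ratio) != 3L || length(sd_ratio) != 3L) {
    stop_st("invalid_parameter", "mean_ratio and sd_ratio must have one value per site (S1, S2, S3)")
  }
  if (any(mean_ratio < 0) || any(sd_ratio < 0) || mean_task_time < 0 || sd_task_time < 0) {
    stop_st("invalid_parameter", "group means and SDs must be non-negative")
  }
  structure(list(
    group_label = group_label, n_subjects = as.integer(n_subjects),
    mean_ratio = stats::setNames(as.numeric(mean_ratio), c("S1", "S2", "S3")),
    sd_ratio = stats::setNames(as.numeric(sd_ratio), c("S1", "S2", "S3")),
    mean_task_time = mean_task_time, sd_task_time = sd_task_time,
    mean_ftm = mean_ftm, sd_ftm = sd_ftm
  ), class = "group_params")
}

#' Default cohort composition
#'
#' The four study-like groups with their published summary statistics:
#' 18 controls, 6 ET-0, 5 ET+1 and 6 ET+2 subjects; per-site mean (SD) PSD
#' ratios, mean (SD) task times, and ET-group clinical FTM scores.
#'
#' @return A list of four [group_params()] objects.
#' @export
default_group_params <- function() {
  list(
    group_params("control", 18,
                 mean_ratio = c(0.55, 0.79, 0.81), sd_ratio = c(0.37, 1.12, 0.60),
                 mean_task_time = 12.64, sd_task_time = 5.53),
    group_params("ET0", 6,
                 mean_ratio = c(2.15, 2.84, 0.88), sd_ratio = c(1.66, 2.42, 1.14),
                 mean_task_time = 20.53, sd_task_time = 14.23,
                 mean_ftm = 16.0, sd_ftm = 9.2),
    group_params("ET1plus", 5,
                 mean_ratio = c(3.90, 5.16, 0.97), sd_ratio = c(2.59, 5.59, 0.95),
                 mean_task_time = 19.82, sd_task_time = 8.04,
                 mean_ftm = 20.4, sd_ftm = 3.8),
    group_params("ET2plus", 6,
                 mean_ratio = c(4.74, 6.96, 2.09), sd_ratio = c(1.82, 6.24, 2.59),
                 mean_task_time = 26.92, sd_task_time = 14.95,
                 mean_ftm = 36.25, sd_ftm = 12.24)
  )
}

#' Tremor component specification
#'
#' Parameters of the injected tremor oscillation: an amplitude-modulated
#' sinusoid strictly inside the 4-12 Hz ET band, plus white sensor noise.
#'
#' @param tremor_freq Tremor frequency in Hz, inside (4, 12).
#' @param tremor_amplitude Tremor acceleration amplitude (m/s^2, >= 0).
#' @param am_depth Amplitude-modulation depth, fraction in `[0, 1)`.
#' @param am_rate Amplitude-modulation rate in Hz (< 1).
#' @param noise_sd White-noise SD per axis (m/s^2).
#' @return A list of class `"tremor_spec"`.
#' @export
tremor_spec <- function(tremor_freq = 6, tremor_amplitude = 0.1,
                        am_depth = 0.2, am_rate = 0.4, noise_sd = 0.01) {
  if (!is_scalar_num(tremor_freq) || tremor_freq <= 4 || tremor_freq >= 12) {
    stop_st("invalid_parameter", "tremor_freq must lie strictly inside (4, 12) Hz")
  }
  if (!is_scalar_num(tremor_amplitude) || tremor_amplitude < 0) {
    stop_st("invalid_parameter", "tremor_amplitude must be >= 0")
  }
  if (am_depth < 0 || am_depth >= 1) stop_st("invalid_parameter", "am_depth must be in [0, 1)")
  if (am_rate <= 0 || am_rate >= 1) stop_st("invalid_parameter", "am_rate must be in (0, 1) Hz")
  if (noise_sd < 0) stop_st("invalid_parameter", "noise_sd must be >= 0")
  structure(list(tremor_freq = tremor_freq, tremor_amplitude = tremor_amplitude,
                 am_depth = am_depth, am_rate = am_rate, noise_sd = noise_sd),
            class = "tremor_spec")
}

#' Simulate a pen trace of an Archimedes-spiral drawing
#'
#' The pen follows the Archimedes spiral r = a*theta at constant angular
#' rate, spanning `n_turns` full turns over `duration_drawing` seconds, with
#' pen-up (pressure 0) lead-in and trail-out intervals at the spiral centre
#' and end.  Pressure is positive exactly during the drawing interval, so the
#' pen-down sample count is `round(duration_drawing * fs_pen)`.
#'
#' @param duration_drawing Drawing (pen-down) duration in seconds.
#' @param n_turns Number of spiral turns (>= 1).
#' @param fs_pen Tablet sampling rate in Hz.
#' @param lead_pen_up,trail_pen_up Pen-up lead/trail durations in seconds.
#' @param r_max Outer spiral radius in mm (default 60).
#' @param seed Optional seed; randomises the spiral's starting orientation on
#'   the tablet.
#' @return A [pen_trace()].
#' @export
synth_spiral_pen <- function(duration_drawing, n_turns = 3, fs_pen = 100,
                             lead_pen_up = 1, trail_pen_up = lead_pen_up,
                             r_max = 60, seed = NULL) {
  if (!is_scalar_num(duration_drawing) || duration_drawing <= 0) {
    stop_st("invalid_parameter", "duration_drawing must be positive")
  }
  if (!is_count(n_turns)) stop_st("invalid_parameter", "n_turns must be a positive integer")
  if (!is_scalar_num(fs_pen) || fs_pen <= 0) stop_st("invalid_parameter", "fs_pen must be positive")
  if (lead_pen_up < 0 || trail_pen_up < 0) stop_st("invalid_parameter", "pen-up durations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phi0 <- if (is.null(seed)) 0 else stats::runif(1, 0, 2 * pi)

  n_down <- round(duration_drawing * fs_pen)
  n_lead <- round(lead_pen_up * fs_pen)
  n_trail <- round(trail_pen_up * fs_pen)
  n <- n_lead + n_down + n_trail
  t <- (seq_len(n) - 1L) / fs_pen

  theta <- seq(0, 2 * pi * n_turns, length.out = n_down)
  a <- r_max / (2 * pi * n_turns)
  x_draw <- a * theta * cos(theta + phi0)
  y_draw <- a * theta * sin(theta + phi0)

  x <- c(rep(x_draw[1L], n_lead), x_draw, rep(x_draw[n_down], n_trail))
  y <- c(rep(y_draw[1L], n_lead), y_draw, rep(y_draw[n_down], n_trail))
  pressure <- c(rep(0, n_lead), rep(0.8, n_down), rep(0, n_trail))
  pen_trace(t, x, y, pressure, fs = fs_pen)
}

# Fixed sensor-frame geometry shared by the generator: unit direction of the
# tremor/wobble axis and the mapping of the tablet plane into the sensor
# frame.  Gravity lies along +z, so the vector magnitude is, to first order,
# gravity plus the z-projection of the dynamic acceleration.
.synth_geometry <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(
    tremor_dir = c(0.36, 0.48, 0.80),            # already unit length
    plane_x = unit(c(0.85, 0.15, 0.50)),
    plane_y = unit(c(-0.15, 0.85, 0.50))
  )
}

#' Simulate a triaxial accelerometer trace for a drawing session
#'
#' Composes the voluntary drawing acceleration (second finite difference of
#' the pen trajectory, low-pass smoothed at 3.5 Hz and mapped into the sensor
#' frame), a band-limited corrective "wobble" in the voluntary band, an
#' amplitude-modulated tremor sinusoid, white sensor noise, and a constant
#' gravity offset on the z axis.
#'
#' @param pen A [pen_trace()] covering the session.
#' @param spec A [tremor_spec()].
#' @param site_gain Multiplier on the tremor amplitude at this site.
#' @param fs Accelerometer sampling rate in Hz (default 148.1).
#' @param site Sensor site label for the output trace.
#' @param seed Optional seed; fixes wobble, tremor phases and noise.
#' @param wobble_sd SD (m/s^2) of the corrective-wobble component along the
#'   tremor axis; this is what gives the voluntary band its power.
#' @param wobble_band Frequency range of the wobble tones in Hz.
#' @param n_wobble_tones Number of random tones summed for the wobble.
#' @param gravity Gravity magnitude added to the z axis (m/s^2).
#' @return An [accel_trace()].
#' @export
synth_accel <- function(pen, spec = tremor_spec(), site_gain = 1, fs = 148.1,
                        site = "S2", seed = NULL,
                        wobble_sd = 0.05, wobble_band = c(0.9, 3.3),
                        n_wobble_tones = 12, gravity = 9.80665) {
  stopifnot(inherits(pen, "pen_trace"), inherits(spec, "tremor_spec"))
  if (fs <= 2 * spec$tremor_freq) {
    stop_st("aliasing_error", "fs = %g Hz cannot represent a %g Hz tremor (need fs > %g Hz)",
            fs, spec$tremor_freq, 2 * spec$tremor_freq)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(min(pen$t), max(pen$t), by = 1 / fs)
  n <- length(t)
  geom <- .synth_geometry()

  # voluntary: pen trajectory (mm -> m) resampled, twice differenced
  xs <- stats::spline(pen$t, pen$x, xout = t)$y / 1000
  ys <- stats::spline(pen$t, pen$y, xout = t)$y / 1000
  d2 <- function(p) {
    acc <- c(0, diff(p, differences = 2), 0) * fs^2
    bf <- signal::butter(4, 3.5 / (fs / 2), type = "low")
    filtfilt_zp(bf$b, bf$a, acc, round(3 * fs / 3.5))
  }
  d2x <- d2(xs)
  d2y <- d2(ys)

  # corrective wobble: sum of tones confined to the voluntary band, with
  # exact variance wobble_sd^2 in expectation and no power above the band
  fk <- stats::runif(n_wobble_tones, wobble_band[1L], wobble_band[2L])
  ph <- stats::runif(n_wobble_tones, 0, 2 * pi)
  wob <- wobble_sd * sqrt(2 / n_wobble_tones) *
    rowSums(sin(outer(t, 2 * pi * fk) + rep(ph, each = n)))

  # amplitude-modulated tremor tone
  trem <- numeric(n)
  if (spec$tremor_amplitude > 0) {
    ph_am <- stats::runif(1, 0, 2 * pi)
    ph_tr <- stats::runif(1, 0, 2 * pi)
    trem <- site_gain * spec$tremor_amplitude *
      (1 + spec$am_depth * sin(2 * pi * spec$am_rate * t + ph_am)) *
      sin(2 * pi * spec$tremor_freq * t + ph_tr)
  }

  ax <- d2x * geom$plane_x[1L] + d2y * geom$plane_y[1L] + (wob + trem) * geom$tremor_dir[1L]
  ay <- d2x * geom$plane_x[2L] + d2y * geom$plane_y[2L] + (wob + trem) * geom$tremor_dir[2L]
  az <- d2x * geom$plane_x[3L] + d2y * geom$plane_y[3L] + (wob + trem) * geom$tremor_dir[3L] + gravity
  if (spec$noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, spec$noise_sd)
    ay <- ay + stats::rnorm(n, 0, spec$noise_sd)
    az <- az + stats::rnorm(n, 0, spec$noise_sd)
  }
  accel_trace(t, ax, ay, az, site = site, fs = fs)
}

#' Calibrate a tremor amplitude for a target PSD ratio
#'
#' Inverts the band-power ratio: a sinusoid of amplitude A carries power
#' A^2/2, so the amplitude that raises the tremor band to `target_ratio`
#' times the measured voluntary-band power `P_low` is
#' `A = sqrt(2 * target_ratio * P_low)`.
#'
#' @param target_ratio Desired PSD ratio (>= 0).
#' @param voluntary A filtered [magnitude_signal()] of the voluntary-only
#'   (tremor-free) session, from which the voluntary-band power is measured.
#' @param tremor_freq Tremor frequency the amplitude is intended for (Hz);
#'   must lie above the voluntary band.
#' @param band_low Voluntary band in Hz (default `c(0.5, 4)`).
#' @return The magnitude-domain tremor amplitude A.
#' @export
calibrate_amplitude <- function(target_ratio, voluntary, tremor_freq = 6,
                                band_low = c(0.5, 4)) {
  if (!is_scalar_num(target_ratio) || target_ratio < 0) {
    stop_st("invalid_parameter", "target_ratio must be >= 0")
  }
  stopifnot(inherits(voluntary, "magnitude_signal"))
  if (tremor_freq <= band_low[2L]) {
    stop_st("invalid_parameter", "tremor_freq must lie above the voluntary band")
  }
  if (target_ratio == 0) return(0)
  p_low <- band_power(voluntary, band_low)
  if (p_low <= .Machine$double.eps) {
    stop_st("division_by_zero", "voluntary signal has no power in [%g, %g) Hz", band_low[1L], band_low[2L])
  }
  sqrt(2 * target_ratio * p_low)
}

#' Generate a complete synthetic cohort
#'
#' For each subject: draws a task-time target and per-site PSD-ratio targets
#' from the group's moment-matched gamma distributions (non-negative support,
#' exact configured mean and SD; SD 0 degenerates to the mean), a tremor
#' frequency uniform on 4.5-11.5 Hz, and a clinical FTM score consistent with
#' the severity model plus Gaussian residual; then synthesises the pen trace
#' and three accelerometer traces, calibrating the injected tremor per site
#' so the extracted PSD ratio hits the drawn target.
#'
#' Two blinded-rater FTM scores are produced by adding independent rater
#' noise to the latent score; controls carry no FTM.  All randomness derives
#' from `seed`, and regeneration with the same arguments is bit-identical.
#'
#' @param params List of [group_params()] (default [default_group_params()]).
#' @param seed Integer seed for the cohort.
#' @param fs_accel,fs_pen Sampling rates in Hz.
#' @param n_turns Spiral turns per drawing.
#' @param am_depth,am_rate,noise_sd Tremor-spec nuisance parameters shared by
#'   all subjects, see [tremor_spec()].
#' @param wobble_sd Voluntary-band wobble SD (m/s^2), see [synth_accel()].
#' @param ftm_coefs Severity-model coefficients (intercept, per-second,
#'   per-ratio-unit) used to generate latent FTM scores.
#' @param ftm_resid_sd Residual SD of the latent FTM around the model (FTM
#'   points).
#' @param rater_sd Per-rater scoring noise SD (FTM points).
#' @param min_task_time Floor on drawn task times in seconds, keeping every
#'   recording long enough for spectral estimation.
#' @return An object of class `"tremor_cohort"`: list with `subjects` (each
#'   holding `pen`, `accel$S1..S3`, `clinical`, and the drawn `targets`),
#'   plus the generator settings.
#' @export
make_cohort <- function(params = default_group_params(), seed = 1,
                        fs_accel = 148.1, fs_pen = 100, n_turns = 3,
                        am_depth = 0.2, am_rate = 0.4, noise_sd = 0.01,
                        wobble_sd = 0.05,
                        ftm_coefs = c(8.2439, 0.2791, 1.9890),
                        ftm_resid_sd = 8.158, rater_sd = 2.5,
                        min_task_time = 5) {
  if (!length(params)) stop_st("invalid_parameter", "need at least one group")
  lapply(params, function(p) stopifnot(inherits(p, "group_params")))
  set.seed(seed)
  geom <- .synth_geometry()
  uz <- geom$tremor_dir[3L]
  am_power <- sqrt(1 + am_depth^2 / 2)  # AM multiplies tone power by 1 + d^2/2

  subjects <- list()
  for (grp in params) {
    for (j in seq_len(grp$n_subjects)) {
      id <- sprintf("%s_%02d", grp$group_label, j)
      # subject-level draws, fixed order
      task_time <- max(min_task_time, rgamma_ms(1, grp$mean_task_time, grp$sd_task_time))
      rho_target <- vapply(1:3, function(s) rgamma_ms(1, grp$mean_ratio[s], grp$sd_ratio[s]), 0)
      names(rho_target) <- c("S1", "S2", "S3")
      f_trem <- stats::runif(1, 4.5, 11.5)
      ftm_resid <- stats::rnorm(1, 0, ftm_resid_sd)
      rater_eps <- stats::rnorm(2, 0, rater_sd)
      seeds <- sample.int(.Machine$integer.max - 1L, 4L)

      pen <- synth_spiral_pen(task_time, n_turns = n_turns, fs_pen = fs_pen,
                              lead_pen_up = 1, seed = seeds[1L])
      window <- segment_task(pen)

      accel <- list()
      for (s in 1:3) {
        site <- c("S1", "S2", "S3")[s]
        vol <- synth_accel(pen,
                           tremor_spec(f_trem, 0, am_depth, am_rate, noise_sd = 0),
                           fs = fs_accel, site = site, seed = seeds[1L + s],
                           wobble_sd = wobble_sd)
        mag <- highpass(vector_magnitude(slice_accel(vol, window)))
        a_mag <- calibrate_amplitude(rho_target[s], mag, f_trem)
        a_vec <- a_mag / (uz * am_power)
        accel[[site]] <- synth_accel(pen,
                                     tremor_spec(f_trem, a_vec, am_depth, am_rate, noise_sd = noise_sd),
                                     fs = fs_accel, site = site, seed = seeds[1L + s],
                                     wobble_sd = wobble_sd)
      }

      is_control <- grp$group_label == "control"
      ftm_latent <- if (is_control) NA_real_ else {
        min(144, max(0, ftm_coefs[1L] + ftm_coefs[2L] * task_time +
                       ftm_coefs[3L] * rho_target["S2"] + ftm_resid))
      }
      clinical <- list(
        subject_id = id, group_label = grp$group_label,
        ftm_rater1 = if (is_control) NA_real_ else min(144, max(0, ftm_latent + rater_eps[1L])),
        ftm_rater2 = if (is_control) NA_real_ else min(144, max(0, ftm_latent + rater_eps[2L]))
      )
      clinical$ftm_mean <- (clinical$ftm_rater1 + clinical$ftm_rater2) / 2

      subjects[[id]] <- structure(list(
        subject_id = id, group_label = grp$group_label,
        pen = pen, accel = accel, clinical = clinical,
        targets = list(psd_ratio = rho_target, task_time = task_time,
                       tremor_freq = f_trem)
      ), class = "synthetic_subject")
    }
  }
  structure(list(subjects = subjects, params = params, seed = seed,
                 fs_accel = fs_accel, fs_pen = fs_pen, n_turns = n_turns),
            class = "tremor_cohort")
}

#' @export
print.tremor_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group_label, "")
  tab <- table(factor(groups, levels = unique(groups)))
  cat(sprintf("<tremor_cohort> %d subjects (seed %d): %s\n",
              length(x$subjects), x$seed,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Extract features for every subject and site of a cohort
#'
#' @param cohort A `"tremor_cohort"` from [make_cohort()].
#' @param sites Sites to extract (default all three).
#' @param ... Passed to [extract_features()].
#' @return Data frame: `subject_id`, `group`, `site`, `psd_ratio`, `task_time`.
#' @export
cohort_features <- function(cohort, sites = c("S1", "S2", "S3"), ...) {
  stopifnot(inherits(cohort, "tremor_cohort"))
  rows <- lapply(cohort$subjects, function(sub) {
    per_site <- lapply(sites, function(site) {
      cbind(extract_features(sub$accel[[site]], sub$pen, subject_id = sub$subject_id, ...),
            group = sub$group_label, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_site)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject_id", "group", "site", "psd_ratio", "task_time")]
}

#' Join extracted features with the clinical table
#'
#' Produces the analysis-ready cohort table: one row per subject and site,
#' with features and clinical FTM scores.
#'
#' @param cohort A `"tremor_cohort"`.
#' @param ... Passed to [cohort_features()].
#' @return Data frame with columns `subject_id`, `group`, `site`,
#'   `psd_ratio`, `task_time`, `ftm_rater1`, `ftm_rater2`, `ftm_mean`.
#' @export
cohort_table <- function(cohort, ...) {
  feats <- cohort_features(cohort, ...)
  clin <- do.call(rbind, lapply(cohort$subjects, function(sub) {
    data.frame(subject_id = sub$subject_id,
               ftm_rater1 = sub$clinical$ftm_rater1,
               ftm_rater2 = sub$clinical$ftm_rater2,
               ftm_mean = sub$clinical$ftm_mean,
               stringsAsFactors = FALSE)
  }))
  out <- merge(feats, clin, by = "subject_id", sort = FALSE)
  out <- out[order(match(out$subject_id, names(cohort$subjects)), out$site), ]
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk as plain CSV files
#'
#' Emits `<id>_pen.csv` (t, x, y, pressure), `<id>_accel_<site>.csv`
#' (t, ax, ay, az) per subject, and a `cohort.csv` clinical table
#' (subject_id, group, ftm_rater1, ftm_rater2).  Output is deterministic:
#' the same cohort always produces byte-identical files.
#'
#' @param cohort A `"tremor_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tremor_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    write_trace_csv(sub$pen, file.path(dir, sprintf("%s_pen.csv", sub$subject_id)))
    for (site in names(sub$accel)) {
      write_trace_csv(sub$accel[[site]],
                      file.path(dir, sprintf("%s_accel_%s.csv", sub$subject_id, site)))
    }
  }
  clin <- do.call(rbind, lapply(cohort$subjects, function(sub) {
    data.frame(subject_id = sub$subject_id, group = sub$group_label,
               ftm_rater1 = sub$clinical$ftm_rater1,
               ftm_rater2 = sub$clinical$ftm_rater2,
               stringsAsFactors = FALSE)
  }))
  clin$ftm_rater1 <- ifelse(is.na(clin$ftm_rater1), "", format(clin$ftm_rater1, digits = 15, trim = TRUE))
  clin$ftm_rater2 <- ifelse(is.na(clin$ftm_rater2), "", format(clin$ftm_rater2, digits = 15, trim = TRUE))
  utils::write.csv(clin, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a clinical cohort table written by [write_cohort()]
#'
#' @param path Path to `cohort.csv`.
#' @return Data frame with `subject_id`, `group`, `ftm_rater1`, `ftm_rater2`,
#'   `ftm_mean`.
#' @export
read_cohort_csv <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "group", "ftm_rater1", "ftm_rater2"))
  df$ftm_rater1 <- as.numeric(df$ftm_rater1)
  df$ftm_rater2 <- as.numeric(df$ftm_rater2)
  df$ftm_mean <- (df$ftm_rater1 + df$ftm_rater2) / 2
  df
}
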