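#' Construct a validated triaxial accelerometer trace
#'
#' An `accel_trace` is a data frame with columns `t` (seconds, strictly
#' increasing), `ax`, `ay`, `az` (acceleration, any consistent unit), plus a
#' sampling-rate attribute `fs` and the anatomical `site` the sensor was worn
#' at: `S1` hand dorsum, `S2` mid-forearm, `S3` upper arm.
#'
#' Timestamp gaps larger than three nominal sample periods are flagged with a
#' warning and recorded in the `"gaps_flagged"` attribute; samples are never
#' interpolated.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az Numeric acceleration along the three sensor axes.
#' @param site Sensor site, one of `"S1"`, `"S2"`, `"S3"`.
#' @param fs Sampling rate in Hz; estimated as `1 / median(diff(t))` when
#'   omitted.
#' @return A data frame of class `"accel_trace"`.
#' @seealso [read_accel_csv()], [vector_magnitude()], [slice_accel()]
#' @export
accel_trace <- function(t, ax, ay, az, site = "S2", fs = NULL) {
  site <- match.arg(site, c("S1", "S2", "S3"))
  n <- length(t)
  if (!(length(ax) == n && length(ay) == n && length(az) == n)) {
    stop_st("schema_error", "t, ax, ay, az must have equal length")
  }
  if (n < 2L) stop_st("schema_error", "an accelerometer trace needs at least 2 samples")
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop_st("data_error", "timestamps must be finite and strictly increasing")
  }
  if (any(!is.finite(c(ax, ay, az)))) stop_st("data_error", "non-finite acceleration values")
  if (is.null(fs)) fs <- estimate_fs(t)
  if (!is_scalar_num(fs) || fs <= 0) stop_st("invalid_parameter", "fs must be a positive number")
  gaps <- which(diff(t) > 3 / fs)
  if (length(gaps)) {
    warning(sprintf("accel trace (%s): %d timestamp gap(s) exceed 3 sample periods", site, length(gaps)))
  }
  structure(
    data.frame(t = t, ax = ax, ay = ay, az = az),
    fs = fs, site = site, gaps_flagged = gaps,
    class = c("accel_trace", "data.frame")
  )
}

#' Construct a validated pen-tablet trace
#'
#' A `pen_trace` holds the digitizing-tablet stream recorded during spiral
#' drawing: timestamps, pen position and pen-tip pressure.  Pressure equal to
#' zero marks the pen held above the tablet ("pen-up"); any positive pressure
#' is "pen-down".
#'
#' @param t Numeric timestamps in seconds, strictly increasing.
#' @param x,y Pen position (mm or device units).
#' @param pressure Non-negative pen-tip pressure.
#' @param fs Sampling rate in Hz; estimated from `t` when omitted.
#' @return A data frame of class `"pen_trace"`.
#' @seealso [label_strokes()], [segment_task()], [synth_spiral_pen()]
#' @export
pen_trace <- function(t, x, y, pressure, fs = NULL) {
  n <- length(t)
  if (!(length(x) == n && length(y) == n && length(pressure) == n)) {
    stop_st("schema_error", "t, x, y, pressure must have equal length")
  }
  if (n < 2L) stop_st("schema_error", "a pen trace needs at least 2 samples")
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop_st("data_error", "timestamps must be finite and strictly increasing")
  }
  if (any(!is.finite(c(x, y, pressure)))) stop_st("data_error", "non-finite pen values")
  if (any(pressure < 0)) stop_st("data_error", "pen pressure must be non-negative")
  if (is.null(fs)) fs <- estimate_fs(t)
  structure(
    data.frame(t = t, x = x, y = y, pressure = pressure),
    fs = fs, class = c("pen_trace", "data.frame")
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "<accel_trace> site %s, %d samples @ %.6g Hz, %.6g-%.6g s\n",
    attr(x, "site"), nrow(x), attr(x, "fs"), x$t[1], x$t[nrow(x)]
  ))
  invisible(x)
}

#' @export
print.pen_trace <- function(x, ...) {
  ndown <- sum(x$pressure > 0)
  cat(sprintf(
    "<pen_trace> %d samples @ %.6g Hz, %d pen-down (%.1f%%)\n",
    nrow(x), attr(x, "fs"), ndown, 100 * ndown / nrow(x)
  ))
  invisible(x)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_st("schema_error", "file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = TRUE),
    error = function(e) stop_st("schema_error", "cannot parse %s: %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_st("schema_error", "%s: missing column(s) %s", path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) < 2L) stop_st("schema_error", "%s: need at least 2 data rows", path)
  df
}

#' Read an accelerometer CSV file
#'
#' Reads a per-sensor CSV with header columns `t, ax, ay, az` (any column
#' order; parsing is header-keyed) and validates it into an [accel_trace()].
#' The sampling rate is estimated as the reciprocal median timestamp step and
#' compared against the nominal rate; a deviation beyond 5% is logged as a
#' warning and the estimated rate is used.
#'
#' @param path Path to the CSV file.
#' @param site Sensor site, one of `"S1"`, `"S2"`, `"S3"`.
#' @param nominal_fs Nominal sampling rate in Hz (default 148.1, the rate of
#'   the wearable IMUs this pipeline was designed around).
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path, site = "S2", nominal_fs = 148.1) {
  df <- read_csv_checked(path, c("t", "ax", "ay", "az"))
  if (any(!is.finite(df$t)) || any(diff(df$t) <= 0)) {
    stop_st("data_error", "%s: timestamps must be finite and strictly increasing", path)
  }
  fs_est <- estimate_fs(df$t)
  if (abs(fs_est - nominal_fs) / nominal_fs > 0.05) {
    warning(sprintf(
      "%s: estimated sampling rate %.3f Hz deviates >5%% from nominal %.3f Hz; using the estimate",
      path, fs_est, nominal_fs
    ))
  }
  accel_trace(df$t, df$ax, df$ay, df$az, site = site, fs = fs_est)
}

#' Read a pen-tablet CSV file
#'
#' Reads a tablet stream CSV with header columns `t, x, y, pressure` (any
#' column order) and validates it into a [pen_trace()].
#'
#' @param path Path to the CSV file.
#' @return A [pen_trace()].
#' @export
read_pen_csv <- function(path) {
  df <- read_csv_checked(path, c("t", "x", "y", "pressure"))
  pen_trace(df$t, df$x, df$y, df$pressure)
}

#' Write traces back to the CSV dialect the readers expect
#'
#' Plain UTF-8 CSV, '.' decimal separator, header row, full double precision.
#'
#' @param trace An [accel_trace()] or [pen_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, c("accel_trace", "pen_trace")))
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(col) if (is.numeric(col)) format(col, digits = 15, trim = TRUE) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
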