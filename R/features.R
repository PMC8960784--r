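#' Construct a magnitude signal
#'
#' Container for a scalar acceleration-magnitude time series.  Before
#' filtering the magnitude is non-negative by construction; after high-pass
#' filtering it is signed and the `filtered` flag is set.
#'
#' @param t Timestamps in seconds.
#' @param m Magnitude values.
#' @param fs Sampling rate in Hz.
#' @param filtered Logical; has the signal been high-pass filtered?
#' @return An object of class `"magnitude_signal"`.
#' @export
magnitude_signal <- function(t, m, fs, filtered = FALSE) {
  if (length(t) != length(m)) stop_st("schema_error", "t and m must have equal length")
  if (!filtered && any(m < 0)) stop_st("data_error", "unfiltered magnitude must be non-negative")
  structure(list(t = t, m = m, fs = fs, filtered = filtered),
            class = "magnitude_signal")
}

#' @export
print.magnitude_signal <- function(x, ...) {
  cat(sprintf("<magnitude_signal> %d samples @ %.6g Hz, %s\n",
              length(x$m), x$fs, if (x$filtered) "filtered" else "unfiltered"))
  invisible(x)
}

#' Acceleration vector magnitude
#'
#' Collapses the three acceleration axes to the orientation-invariant scalar
#' \eqn{\sqrt{a_x^2 + a_y^2 + a_z^2}}.  Because the Euclidean norm is
#' invariant under rotation of the sensor frame, the result does not depend
#' on the angle at which the sensor was strapped to the arm.
#'
#' @param accel An [accel_trace()].
#' @return An unfiltered [magnitude_signal()].
#' @export
vector_magnitude <- function(accel) {
  stopifnot(inherits(accel, "accel_trace"))
  magnitude_signal(accel$t, sqrt(accel$ax^2 + accel$ay^2 + accel$az^2),
                   fs = attr(accel, "fs"), filtered = FALSE)
}

# Steady-state initial history for signal::filter so that a constant input
# produces its steady-state output from the first sample (no start-up
# transient on the DC component).
filtfilt_zp <- function(b, a, x, padlen) {
  nf <- max(length(a), length(b))
  nx <- length(x)
  padlen <- max(nf, min(nx - 1L, padlen))
  h1 <- sum(b) / sum(a)
  onepass <- function(z) {
    n <- length(z)
    ext <- c(2 * z[1L] - z[(padlen + 1L):2L], z,
             2 * z[n] - z[(n - 1L):(n - padlen)])
    y <- signal::filter(b, a, ext,
                        init.x = rep(ext[1L], nf - 1L),
                        init.y = rep(ext[1L] * h1, nf - 1L))
    y[(padlen + 1L):(padlen + n)]
  }
  rev(onepass(rev(onepass(x))))
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes the gravity offset and slow drift from the magnitude signal with a
#' Butterworth high-pass applied forward and backward (zero phase lag).  Edge
#' effects are controlled by odd-reflection padding with steady-state initial
#' conditions, so a constant input is rejected essentially to machine
#' precision (far beyond 60 dB).
#'
#' @param sig A [magnitude_signal()].
#' @param cutoff High-pass cutoff frequency in Hz (default 0.5).
#' @param order Butterworth order (default 4); applied twice, so the
#'   effective roll-off is 8th order.
#' @return A filtered [magnitude_signal()].
#' @export
highpass <- function(sig, cutoff = 0.5, order = 4) {
  stopifnot(inherits(sig, "magnitude_signal"))
  fs <- sig$fs
  if (fs <= 2 * cutoff) stop_st("invalid_parameter", "fs (%g Hz) must exceed twice the cutoff (%g Hz)", fs, cutoff)
  minlen <- 3L * (2L * order + 1L)
  if (length(sig$m) < minlen) {
    stop_st("too_short", "signal has %d samples; at least %d needed for order-%d zero-phase filtering",
            length(sig$m), minlen, order)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  padlen <- round(3 * fs / cutoff)
  magnitude_signal(sig$t, filtfilt_zp(bf$b, bf$a, sig$m, padlen), fs = fs, filtered = TRUE)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window: the signal is split into
#' overlapping segments, each segment is mean-detrended, windowed and
#' Fourier-transformed, and the one-sided power densities are averaged.
#' Defaults (4 s segments, 50% overlap) give 0.25 Hz resolution, enough to
#' resolve the 0.5 Hz band edge.  Signals shorter than one segment fall back
#' to a single-segment periodogram with a warning.
#'
#' @param sig A [magnitude_signal()], or a numeric vector (then `fs` must be
#'   given).
#' @param fs Sampling rate in Hz (ignored when `sig` is a magnitude signal).
#' @param segment_s Segment length in seconds (default 4).
#' @param overlap Fractional overlap between segments in `[0, 1)` (default 0.5).
#' @return A list of class `"psd_estimate"` with elements `freq` (Hz) and
#'   `psd` (power per Hz); integrating `psd` over frequency recovers the
#'   signal variance (Parseval).
#' @export
welch_psd <- function(sig, fs = NULL, segment_s = 4, overlap = 0.5) {
  if (inherits(sig, "magnitude_signal")) {
    x <- sig$m
    fs <- sig$fs
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) stop_st("invalid_parameter", "fs is required for a bare numeric signal")
  }
  if (!is_scalar_num(fs) || fs <= 0) stop_st("invalid_parameter", "fs must be positive")
  if (overlap < 0 || overlap >= 1) stop_st("invalid_parameter", "overlap must be in [0, 1)")
  n <- length(x)
  nperseg <- round(segment_s * fs)
  if (nperseg < 8L) stop_st("invalid_parameter", "segment too short (%d samples)", nperseg)
  if (n < nperseg) {
    warning(sprintf("signal (%d samples) shorter than one %g-s segment; using a single-segment periodogram", n, segment_s))
    nperseg <- n
  }
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg)
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]  # one-sided
    acc <- acc + p
  }
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / nperseg,
                 psd = acc / length(starts),
                 fs = fs, nperseg = nperseg, n_segments = length(starts)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d frequencies to %.6g Hz, %d segment(s) of %d samples\n",
              length(x$freq), max(x$freq), x$n_segments, x$nperseg))
  invisible(x)
}

#' Integrated band power
#'
#' Integrates the Welch PSD over a frequency band with the trapezoidal rule.
#' The integral runs over the continuous interval from `band[1]` to
#' `band[2]`; band-edge assignment of a pure tone sitting exactly on an edge
#' is therefore a documented convention of the adjacent band definitions
#' (`[0.5, 4)` voluntary, `[4, 12]` tremor), not of this function.
#'
#' @param sig A [magnitude_signal()] (filtered) or numeric vector with `fs`.
#' @param band Length-2 numeric, band edges in Hz, within `[0, fs/2]`.
#' @param fs,segment_s,overlap Passed to [welch_psd()].
#' @return Non-negative band power (signal units squared).
#' @export
band_power <- function(sig, band, fs = NULL, segment_s = 4, overlap = 0.5) {
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop_st("invalid_band", "band must be (f1, f2) with f1 < f2")
  }
  est <- welch_psd(sig, fs = fs, segment_s = segment_s, overlap = overlap)
  if (band[1L] < 0 || band[2L] > est$fs / 2) {
    stop_st("invalid_band", "band [%g, %g] Hz outside [0, %g] Hz", band[1L], band[2L], est$fs / 2)
  }
  idx <- est$freq >= band[1L] & est$freq <= band[2L]
  trapz(est$freq[idx], est$psd[idx])
}

#' Tremor-band to voluntary-band PSD ratio
#'
#' The central tremor feature: integrated PSD in the tremor band (default
#' 4-12 Hz) divided by integrated PSD in the voluntary-movement band
#' (default 0.5-4 Hz), computed on the high-pass-filtered acceleration
#' vector magnitude.  The ratio is dimensionless and invariant to uniform
#' scaling of the input, so it needs no amplitude normalisation and is
#' comparable across subjects and sensor units.
#'
#' @param sig A filtered [magnitude_signal()] of at least 2 s duration.
#' @param band_low Voluntary band in Hz (default `c(0.5, 4)`).
#' @param band_high Tremor band in Hz (default `c(4, 12)`).
#' @param segment_s,overlap Welch parameters, see [welch_psd()].
#' @return An object of class `"band_powers"`: list with `p_low`, `p_high`,
#'   `ratio` and the band definitions.
#' @export
psd_ratio <- function(sig, band_low = c(0.5, 4), band_high = c(4, 12),
                      segment_s = 4, overlap = 0.5) {
  stopifnot(inherits(sig, "magnitude_signal"))
  if (!sig$filtered) {
    warning("computing a PSD ratio on an unfiltered magnitude signal; high-pass filter first")
  }
  dur <- (length(sig$m) - 1L) / sig$fs
  if (dur < 2) stop_st("too_short", "signal spans %.3f s; at least 2 s needed for a PSD ratio", dur)
  est <- welch_psd(sig, segment_s = segment_s, overlap = overlap)
  integ <- function(band) {
    idx <- est$freq >= band[1L] & est$freq <= band[2L]
    trapz(est$freq[idx], est$psd[idx])
  }
  p_low <- integ(band_low)
  p_high <- integ(band_high)
  floor_p <- max(trapz(est$freq, est$psd), .Machine$double.eps) * 1e-12
  if (p_low <= floor_p) {
    stop_st("undefined_ratio", "voluntary-band power is below the numerical floor; ratio undefined")
  }
  structure(list(p_low = p_low, p_high = p_high, ratio = p_high / p_low,
                 band_low = band_low, band_high = band_high),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> P[%g-%g Hz] = %.4g, P[%g-%g Hz] = %.4g, ratio = %.4g\n",
              x$band_low[1], x$band_low[2], x$p_low,
              x$band_high[1], x$band_high[2], x$p_high, x$ratio))
  invisible(x)
}

#' Extract the per-subject feature pair (PSD ratio, task time)
#'
#' Full feature path for one sensor site: segment the task from the pen
#' pressure channel, slice the accelerometer trace to the task window, take
#' the vector magnitude, high-pass filter it, and form the band-power ratio.
#' Task time is the pen-down duration from the same segmentation.
#'
#' @param accel An [accel_trace()].
#' @param pen The matching [pen_trace()].
#' @param subject_id Identifier copied into the output row.
#' @param clock_offset Pen-to-IMU clock offset in seconds (default 0).
#' @param cutoff,filter_order High-pass parameters, see [highpass()].
#' @param band_low,band_high,segment_s,overlap Spectral parameters, see
#'   [psd_ratio()].
#' @return One-row data frame: `subject_id`, `site`, `psd_ratio`, `task_time`.
#' @export
extract_features <- function(accel, pen, subject_id = NA_character_,
                             clock_offset = 0, cutoff = 0.5, filter_order = 4,
                             band_low = c(0.5, 4), band_high = c(4, 12),
                             segment_s = 4, overlap = 0.5) {
  window <- segment_task(pen)
  sliced <- slice_accel(accel, window, clock_offset = clock_offset)
  mag <- highpass(vector_magnitude(sliced), cutoff = cutoff, order = filter_order)
  bp <- psd_ratio(mag, band_low = band_low, band_high = band_high,
                  segment_s = segment_s, overlap = overlap)
  data.frame(
    subject_id = subject_id,
    site = attr(accel, "site"),
    psd_ratio = bp$ratio,
    task_time = window$pen_down_duration,
    stringsAsFactors = FALSE
  )
}
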