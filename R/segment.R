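#' Label pen-up / pen-down strokes
#'
#' Partitions a pen trace into maximal runs of constant pen state: samples
#' with pressure > 0 form `pen_down` strokes, samples with pressure = 0 form
#' `pen_up` strokes.  Every sample belongs to exactly one stroke.
#'
#' An optional minimum-stroke-duration filter guards against pressure-sensor
#' chatter in real recordings: strokes shorter than `min_duration` seconds
#' are merged into the neighbouring stroke of opposite kind (off by default,
#' matching a clean pressure channel).
#'
#' @param pen A [pen_trace()].
#' @param min_duration Minimum stroke duration in seconds; 0 disables the
#'   filter.
#' @return A data frame with columns `kind` (`"pen_up"`/`"pen_down"`),
#'   `start`, `end` (1-based sample indices, inclusive) and `n` samples.
#' @export
label_strokes <- function(pen, min_duration = 0) {
  stopifnot(inherits(pen, "pen_trace"))
  down <- pen$pressure > 0
  r <- rle(down)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  strokes <- data.frame(
    kind = ifelse(r$values, "pen_down", "pen_up"),
    start = starts, end = ends, n = r$lengths,
    stringsAsFactors = FALSE
  )
  if (min_duration > 0 && nrow(strokes) > 1L) {
    fs <- attr(pen, "fs")
    repeat {
      short <- which(strokes$n / fs < min_duration)
      if (!length(short)) break
      i <- short[1L]
      # merge the short stroke into its longer neighbour
      j <- if (i == 1L) 2L else i - 1L
      keep <- strokes[-i, , drop = FALSE]
      tgt <- if (i == 1L) 1L else i - 1L
      keep$start[tgt] <- min(strokes$start[c(i, j)])
      keep$end[tgt] <- max(strokes$end[c(i, j)])
      keep$n[tgt] <- keep$end[tgt] - keep$start[tgt] + 1L
      # re-merge adjacent strokes that now share a kind
      strokes <- keep
      k <- 1L
      while (k < nrow(strokes)) {
        if (strokes$kind[k] == strokes$kind[k + 1L]) {
          strokes$end[k] <- strokes$end[k + 1L]
          strokes$n[k] <- strokes$end[k] - strokes$start[k] + 1L
          strokes <- strokes[-(k + 1L), , drop = FALSE]
        } else k <- k + 1L
      }
      rownames(strokes) <- NULL
    }
  }
  strokes
}

#' Delimit the drawing task and compute task time T
#'
#' The task window runs from the first to the last pen-down sample.  The
#' task-time feature `T` is the total pen-down duration: the count of
#' pen-down samples divided by the pen sampling rate, so pen-up gaps inside
#' the task do not count towards `T` even though they lie inside the window.
#'
#' @param pen A [pen_trace()].
#' @return An object of class `"task_window"`: list with `t_start`, `t_end`
#'   (seconds), `pen_down_duration` (the feature `T`, seconds) and
#'   `n_pen_down` (sample count).
#' @export
segment_task <- function(pen) {
  stopifnot(inherits(pen, "pen_trace"))
  down <- which(pen$pressure > 0)
  if (!length(down)) stop_st("no_pen_down", "pen trace contains no pen-down sample")
  fs <- attr(pen, "fs")
  structure(
    list(
      t_start = pen$t[down[1L]],
      t_end = pen$t[down[length(down)]],
      pen_down_duration = length(down) / fs,
      n_pen_down = length(down)
    ),
    class = "task_window"
  )
}

#' @export
print.task_window <- function(x, ...) {
  cat(sprintf(
    "<task_window> %.3f-%.3f s, pen-down duration T = %.3f s (%d samples)\n",
    x$t_start, x$t_end, x$pen_down_duration, x$n_pen_down
  ))
  invisible(x)
}

#' Slice an accelerometer trace to the task window
#'
#' Keeps samples with `t` in the closed interval `[t_start, t_end]` (after
#' applying any pen/IMU clock offset).  The slice must overlap the window and
#' span at least `min_duration` seconds, below which downstream spectral
#' estimates would be unreliable.
#'
#' @param accel An [accel_trace()].
#' @param window A `"task_window"` from [segment_task()].
#' @param clock_offset Constant offset (seconds) added to the window times to
#'   express them on the accelerometer clock; default 0 (shared clock).
#' @param min_duration Minimum slice duration in seconds (default 2).
#' @return An [accel_trace()] restricted to the window.
#' @export
slice_accel <- function(accel, window, clock_offset = 0, min_duration = 2) {
  stopifnot(inherits(accel, "accel_trace"), inherits(window, "task_window"))
  t0 <- window$t_start + clock_offset
  t1 <- window$t_end + clock_offset
  keep <- accel$t >= t0 & accel$t <= t1
  if (!any(keep)) {
    stop_st("alignment_error", "task window [%.3f, %.3f] s does not overlap the accelerometer trace", t0, t1)
  }
  out <- accel[keep, , drop = FALSE]
  if (out$t[nrow(out)] - out$t[1L] < min_duration) {
    stop_st("too_short", "task-window slice spans %.3f s (< %g s required)",
            out$t[nrow(out)] - out$t[1L], min_duration)
  }
  accel_trace(out$t, out$ax, out$ay, out$az,
              site = attr(accel, "site"), fs = attr(accel, "fs"))
}
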