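# Shared fixtures and independent oracles, all built in code.

# Magnitude signal that is a sum of sinusoids: amps[i] * sin(2*pi*freqs[i]*t).
msig <- function(freqs, amps, fs = 148.1, dur = 20, filtered = TRUE, offset = 0) {
  t <- seq(0, dur, by = 1 / fs)
  m <- rep(offset, length(t))
  for (i in seq_along(freqs)) m <- m + amps[i] * sin(2 * pi * freqs[i] * t)
  magnitude_signal(t, m, fs = fs, filtered = filtered)
}

# Uniformly random 3x3 rotation matrix (QR of a Gaussian matrix, det +1).
rand_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))))
}

rotate_trace <- function(accel, R) {
  A <- as.matrix(accel[, c("ax", "ay", "az")]) %*% t(R)
  accel_trace(accel$t, A[, 1], A[, 2], A[, 3],
              site = attr(accel, "site"), fs = attr(accel, "fs"))
}

# Brute-force Mann-Whitney U of group a: pairwise wins (+ half-ties).
brute_u <- function(a, b) {
  wins <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  min(wins, length(a) * length(b) - wins)
}

# Kruskal-Wallis H from the rank formula with tie correction.
kw_oracle <- function(groups) {
  values <- unlist(groups)
  r <- rank(values)
  n <- length(values)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Direct single-periodogram band power (rectangle rule over DFT bins).
periodogram_band_power <- function(x, fs, band) {
  x <- x - mean(x)
  n <- length(x)
  nfreq <- n %/% 2 + 1
  p <- Mod(stats::fft(x)[1:nfreq])^2 / (fs * n)
  p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
  f <- (0:(nfreq - 1)) * fs / n
  sum(p[f >= band[1] & f <= band[2]]) * fs / n
}

# Small fast cohort: all four groups, reduced sizes, milder tails.
small_group_params <- function() {
  list(
    group_params("control", 3, c(0.5, 0.8, 0.8), c(0.3, 0.5, 0.4), 10, 2),
    group_params("ET0", 3, c(2.2, 2.8, 0.9), c(1.0, 1.2, 0.5), 14, 3,
                 mean_ftm = 16, sd_ftm = 6),
    group_params("ET1plus", 2, c(3.9, 5.2, 1.0), c(1.5, 2.0, 0.5), 14, 3,
                 mean_ftm = 20, sd_ftm = 4),
    group_params("ET2plus", 2, c(4.7, 7.0, 2.1), c(1.5, 2.5, 1.0), 18, 4,
                 mean_ftm = 36, sd_ftm = 8)
  )
}

# Feature table shaped like cohort_table() output, built directly from
# separated group distributions (no signal synthesis; for SVM/stats tests).
toy_cohort_table <- function(seed = 1, n = c(control = 12, ET0 = 6, ET1plus = 5, ET2plus = 6)) {
  set.seed(seed)
  mk <- function(group, n, mu_r, mu_t, ftm0) {
    r <- pmax(0.05, stats::rnorm(n, mu_r, 0.6))
    tt <- pmax(4, stats::rnorm(n, mu_t, 2))
    ftm <- if (is.na(ftm0)) rep(NA_real_, n) else pmax(0, ftm0 + 1.9890 * r + stats::rnorm(n, 0, 2))
    data.frame(
      subject_id = sprintf("%s_%02d", group, seq_len(n)), group = group, site = "S2",
      psd_ratio = r, task_time = tt,
      ftm_rater1 = ftm + stats::rnorm(n, 0, 1), ftm_rater2 = ftm + stats::rnorm(n, 0, 1),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    mk("control", n[["control"]], 0.8, 12, NA),
    mk("ET0", n[["ET0"]], 3.0, 18, 12),
    mk("ET1plus", n[["ET1plus"]], 5.2, 19, 16),
    mk("ET2plus", n[["ET2plus"]], 7.0, 25, 28)
  )
  out$ftm_mean <- (out$ftm_rater1 + out$ftm_rater2) / 2
  out
}
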