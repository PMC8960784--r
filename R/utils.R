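# Small shared internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y over grid x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

stop_st <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "spiraltremor_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Gamma draws parameterised by mean and sd (exact first two moments on a
# non-negative support); sd = 0 degenerates to the mean.  Sampling goes
# through the inverse CDF so that draws are coupled across parameter
# settings under a common RNG stream.
rgamma_ms <- function(n, mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  if (sd == 0 || mean == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  stats::qgamma(stats::runif(n), shape = shape, rate = rate)
}

# Estimate a sampling rate from timestamps.
estimate_fs <- function(t) {
  if (length(t) < 2L) stop_st("data_error", "need at least 2 samples to estimate a sampling rate")
  1 / stats::median(diff(t))
}
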