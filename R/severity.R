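#' Fit an FTM severity model by ordinary least squares
#'
#' Regresses clinical Fahn-Tolosa-Marin scores on the sensor features by
#' ordinary least squares.  The canonical bivariate form is
#' `ftm ~ task_time + psd_ratio`; a univariate form `ftm ~ psd_ratio`
#' mirrors the per-sensor regressions.  The returned object reports the
#' coefficient of determination and the root-mean-square error
#' `sqrt(SSE / n)` (population convention; set `rmse_df_correct = TRUE` for
#' `sqrt(SSE / (n - p))`).
#'
#' @param formula Model formula; the response is the FTM score and the
#'   allowed predictors are `task_time` and `psd_ratio`.
#' @param data Data frame holding the variables.
#' @param rmse_df_correct Use the degrees-of-freedom-corrected RMSE
#'   convention (default `FALSE`).
#' @return An object of class `"ftm_model"` with components `coefficients`
#'   (named `(Intercept)`, `task_time`, `psd_ratio`; absent terms are 0),
#'   `r_squared`, `rmse`, `n_obs`, `fit` (the underlying `lm`), `call`.
#' @examples
#' d <- data.frame(task_time = c(10, 15, 20, 25, 30),
#'                 psd_ratio = c(0.5, 2, 4, 6, 8))
#' d$ftm <- 8.2439 + 0.2791 * d$task_time + 1.9890 * d$psd_ratio
#' m <- ftm_severity(ftm ~ task_time + psd_ratio, d)
#' coef(m)
#' predict(m, data.frame(task_time = 20.53, psd_ratio = 2.84))
#' @seealso [published_ftm_model()], [fit_univariate()], [fit_bivariate()]
#' @export
ftm_severity <- function(formula, data, rmse_df_correct = FALSE) {
  mf <- stats::model.frame(formula, data)
  terms_used <- attr(stats::terms(mf), "term.labels")
  bad <- setdiff(terms_used, c("task_time", "psd_ratio"))
  if (length(bad)) stop_st("invalid_parameter", "unknown predictor(s): %s", paste(bad, collapse = ", "))
  n <- nrow(mf)
  p <- length(terms_used) + 1L
  if (n < p + 1L) stop_st("sample_size_error", "need at least %d observations for %d parameters", p + 1L, p)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    stop_st("collinearity_error", "predictors are collinear or constant; model is not identifiable")
  }
  fit <- stats::lm(formula, data = mf)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  coefs <- c("(Intercept)" = 0, task_time = 0, psd_ratio = 0)
  coefs[names(stats::coef(fit))] <- stats::coef(fit)
  structure(list(
    coefficients = coefs,
    r_squared = suppressWarnings(summary(fit)$r.squared),  # exact fits are legal
    rmse = sqrt(sse / (if (rmse_df_correct) n - p else n)),
    n_obs = n,
    fit = fit,
    published = FALSE,
    call = match.call()
  ), class = "ftm_model")
}

#' Per-sensor univariate severity regression
#'
#' OLS of the FTM score on the PSD ratio alone, one sensor site at a time.
#'
#' @param psd_ratio Numeric vector of PSD ratios.
#' @param ftm Numeric vector of FTM scores, same length.
#' @param ... Passed to [ftm_severity()].
#' @return An `"ftm_model"` (with `task_time` coefficient 0).
#' @export
fit_univariate <- function(psd_ratio, ftm, ...) {
  ftm_severity(ftm ~ psd_ratio, data.frame(psd_ratio = psd_ratio, ftm = ftm), ...)
}

#' Bivariate severity regression on task time and PSD ratio
#'
#' @param task_time Numeric vector of task times in seconds.
#' @param psd_ratio Numeric vector of PSD ratios.
#' @param ftm Numeric vector of FTM scores.
#' @param ... Passed to [ftm_severity()].
#' @return An `"ftm_model"`.
#' @export
fit_bivariate <- function(task_time, psd_ratio, ftm, ...) {
  ftm_severity(ftm ~ task_time + psd_ratio,
               data.frame(task_time = task_time, psd_ratio = psd_ratio, ftm = ftm), ...)
}

#' The published severity model
#'
#' The fixed-coefficient severity estimator
#' `FTM = 8.2439 + 0.2791 * T + 1.9890 * rho`, with its reported fit
#' statistics (r^2 = 0.561, RMSE = 8.158 on 17 subjects).  Use it to score
#' new recordings without refitting.
#'
#' @return An `"ftm_model"` with fixed coefficients and no underlying `lm`.
#' @export
published_ftm_model <- function() {
  structure(list(
    coefficients = c("(Intercept)" = 8.2439, task_time = 0.2791, psd_ratio = 1.9890),
    r_squared = 0.561,
    rmse = 8.158,
    n_obs = 17L,
    fit = NULL,
    published = TRUE,
    call = quote(published_ftm_model())
  ), class = "ftm_model")
}

#' @export
coef.ftm_model <- function(object, ...) object$coefficients

#' Predict FTM severity from sensor features
#'
#' Evaluates `FTM = b0 + b1 * task_time + b2 * psd_ratio` and clips the
#' result at 0 (an FTM score cannot be negative).
#'
#' @param object An `"ftm_model"`.
#' @param newdata Data frame with columns `task_time` and/or `psd_ratio` (a
#'   predictor the model does not use may be omitted).
#' @param clip Clip predictions at 0 (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of estimated FTM scores.
#' @export
predict.ftm_model <- function(object, newdata, clip = TRUE, ...) {
  cf <- object$coefficients
  tt <- if (cf[["task_time"]] != 0 || "task_time" %in% names(newdata)) newdata$task_time %||% 0 else 0
  rho <- if (cf[["psd_ratio"]] != 0 || "psd_ratio" %in% names(newdata)) newdata$psd_ratio %||% 0 else 0
  if (any(tt < 0, na.rm = TRUE) || any(rho < 0, na.rm = TRUE)) {
    stop_st("invalid_parameter", "task_time and psd_ratio must be non-negative")
  }
  y <- cf[["(Intercept)"]] + cf[["task_time"]] * tt + cf[["psd_ratio"]] * rho
  if (clip) y <- pmax(y, 0)
  unname(y)
}

#' Convenience wrapper: score one feature pair
#'
#' @param model An `"ftm_model"` (default the published model).
#' @param task_time Task time(s) in seconds.
#' @param psd_ratio PSD ratio(s).
#' @param ... Passed to [predict.ftm_model()].
#' @return Estimated FTM score(s).
#' @export
predict_ftm <- function(model = published_ftm_model(), task_time, psd_ratio, ...) {
  predict(model, data.frame(task_time = task_time, psd_ratio = psd_ratio), ...)
}

#' @export
residuals.ftm_model <- function(object, ...) {
  if (is.null(object$fit)) stop_st("invalid_parameter", "the published model carries no residuals")
  stats::residuals(object$fit)
}

#' @export
fitted.ftm_model <- function(object, ...) {
  if (is.null(object$fit)) stop_st("invalid_parameter", "the published model carries no fitted values")
  stats::fitted(object$fit)
}

#' Simulate FTM scores from a severity model
#'
#' Draws `FTM = b0 + b1*T + b2*rho + e`, `e ~ N(0, rmse)`, clipped at 0.
#'
#' @param object An `"ftm_model"`.
#' @param nsim Number of replicate score vectors.
#' @param seed Optional seed.
#' @param newdata Data frame of `task_time`, `psd_ratio` to simulate at.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated scores.
#' @export
simulate.ftm_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata, clip = FALSE)
  out <- replicate(nsim, pmax(mu + stats::rnorm(length(mu), 0, object$rmse), 0))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
print.ftm_model <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("FTM severity model%s:\n", if (x$published) " (published coefficients)" else ""))
  cat(sprintf("  FTM = %.4f + %.4f * task_time + %.4f * psd_ratio\n",
              cf[["(Intercept)"]], cf[["task_time"]], cf[["psd_ratio"]]))
  cat(sprintf("  r^2 = %.3f, RMSE = %.3f FTM points, n = %d\n", x$r_squared, x$rmse, x$n_obs))
  invisible(x)
}

#' @export
summary.ftm_model <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nUnderlying OLS fit:\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' Observed-versus-fitted plot for a severity model
#'
#' @param x A fitted `"ftm_model"` (not the published constant model).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ftm_model <- function(x, ...) {
  if (is.null(x$fit)) stop_st("invalid_parameter", "the published model carries no data to plot")
  obs <- stats::model.response(stats::model.frame(x$fit))
  fit <- stats::fitted(x$fit)
  graphics::plot(fit, obs, xlab = "Estimated FTM", ylab = "Clinical FTM",
                 main = sprintf("FTM severity model (r^2 = %.3f)", x$r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Inter-rater agreement as squared Pearson correlation
#'
#' @param ftm_rater1,ftm_rater2 Paired score vectors from two raters.
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
interrater_r2 <- function(ftm_rater1, ftm_rater2) {
  ok <- is.finite(ftm_rater1) & is.finite(ftm_rater2)
  a <- ftm_rater1[ok]; b <- ftm_rater2[ok]
  if (length(a) != length(b) || length(a) < 3L) {
    stop_st("sample_size_error", "need at least 3 complete score pairs")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_st("degenerate_input", "a rater's scores are constant; correlation undefined")
  }
  stats::cor(a, b)^2
}
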