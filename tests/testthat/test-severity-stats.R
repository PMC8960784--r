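test_that("univariate severity regression recovers exact linear relations", {
  rho <- c(0.5, 2, 4, 7, 11)
  y <- 15.6031 + 1.7763 * rho
  m <- fit_univariate(rho, y)
  expect_equal(unname(coef(m)[c("(Intercept)", "psd_ratio")]), c(15.6031, 1.7763),
               tolerance = 1e-9)
  expect_equal(coef(m)[["task_time"]], 0)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_lt(m$rmse, 1e-10)

  # no association: r^2 near zero
  set.seed(14)
  m0 <- fit_univariate(runif(200, 0, 8), rnorm(200, 20, 5))
  expect_lt(m0$r_squared, 0.05)

  expect_error(fit_univariate(rep(3, 5), 1:5), class = "collinearity_error")
  expect_error(fit_univariate(1:2, 1:2), class = "sample_size_error")
})

test_that("bivariate severity regression recovers its generating coefficients", {
  set.seed(2)
  tt <- runif(17, 8, 35)
  rho <- runif(17, 0.2, 12)
  y <- 8.2439 + 0.2791 * tt + 1.9890 * rho
  m <- fit_bivariate(tt, rho, y)
  expect_equal(unname(coef(m)), c(8.2439, 0.2791, 1.9890), tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  # residuals orthogonal to each predictor
  yn <- y + rnorm(17, 0, 8.158)
  mn <- fit_bivariate(tt, rho, yn)
  res <- residuals(mn)
  scale <- sqrt(sum(res^2)) * sqrt(sum(tt^2))
  expect_lt(abs(sum(res * tt)) / scale, 1e-8)
  expect_lt(abs(sum(res * rho)) / (sqrt(sum(res^2)) * sqrt(sum(rho^2))), 1e-8)

  # adding a predictor cannot reduce r^2
  expect_gte(mn$r_squared, fit_univariate(rho, yn)$r_squared - 1e-12)
  expect_gte(mn$r_squared, ftm_severity(ftm ~ task_time,
             data.frame(task_time = tt, ftm = yn))$r_squared - 1e-12)

  # RMSE conventions
  expect_equal(mn$rmse, sqrt(sum(res^2) / 17), tolerance = 1e-12)
  mdf <- fit_bivariate(tt, rho, yn, rmse_df_correct = TRUE)
  expect_equal(mdf$rmse, sqrt(sum(res^2) / 14), tolerance = 1e-12)

  expect_error(fit_bivariate(tt, tt, y), class = "collinearity_error")
})

test_that("severity prediction applies the published equation and clips at zero", {
  m <- published_ftm_model()
  expect_equal(predict_ftm(m, 0, 0), 8.2439)
  expect_equal(predict_ftm(m, 20.53, 2.84), 19.63, tolerance = 0.05 / 19.63)
  expect_equal(predict_ftm(m, 19.82, 5.16), 24.0, tolerance = 0.05 / 24)
  expect_equal(predict_ftm(m, 26.92, 6.96), 29.59, tolerance = 0.05 / 29.59)
  expect_error(predict_ftm(m, -1, 2), class = "invalid_parameter")

  # clipping: a fitted model with a negative intercept cannot go below 0
  d <- data.frame(task_time = c(5, 10, 15, 20), psd_ratio = c(1, 3, 2, 5))
  d$ftm <- -30 + 1 * d$task_time + 2 * d$psd_ratio
  mneg <- ftm_severity(ftm ~ task_time + psd_ratio, d)
  expect_equal(predict(mneg, data.frame(task_time = 0, psd_ratio = 0)), 0)
  expect_lt(predict(mneg, data.frame(task_time = 0, psd_ratio = 0), clip = FALSE), 0)

  # simulate() reproduces the model plus residual noise
  sims <- simulate(m, nsim = 200, seed = 4,
                   newdata = data.frame(task_time = rep(20, 50), psd_ratio = rep(3, 50)))
  expect_equal(mean(as.matrix(sims)), predict_ftm(m, 20, 3), tolerance = 0.05)
})

test_that("inter-rater agreement is a squared Pearson correlation", {
  x <- c(4, 9, 16, 22, 30, 41)
  expect_equal(interrater_r2(x, x), 1)
  expect_equal(interrater_r2(x, 2 * x + 3), 1)
  set.seed(31)
  expect_lt(interrater_r2(rnorm(500), rnorm(500)), 0.05)
  expect_error(interrater_r2(x, rep(5, 6)), class = "degenerate_input")
  expect_error(interrater_r2(1:2, 2:3), class = "sample_size_error")
})

test_that("Shapiro-Wilk gate flags non-normal features and stays calibrated", {
  set.seed(41)
  # heavy-tailed mixture: detected as non-Gaussian in nearly all replicates
  hits <- replicate(100, {
    x <- c(rnorm(40), rnorm(10, 0, 6))
    shapiro_wilk(x)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)

  # under normality the p-value is uniform
  pvals <- replicate(200, shapiro_wilk(rnorm(500))$p_value)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  expect_error(shapiro_wilk(rep(2, 10)), class = "degenerate_input")
  expect_error(shapiro_wilk(1:2), class = "sample_size_error")
})

test_that("Mann-Whitney U follows the pairwise-win oracle and its symmetries", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)

  # identical multisets: U = n^2/2 and p near 1
  r <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 8)
  expect_gt(r$p_value, 0.9)

  set.seed(51)
  for (i in 1:20) {
    a <- sample(1:40, sample(3:10, 1), replace = TRUE)
    b <- sample(1:40, sample(3:10, 1), replace = TRUE)
    r <- mann_whitney_u(a, b)
    expect_equal(r$statistic, brute_u(a, b))
    sw <- mann_whitney_u(b, a)   # symmetry in the group order
    expect_equal(sw$statistic, r$statistic)
    expect_equal(sw$p_value, r$p_value)
  }

  # exact enumeration vs normal approximation agree for moderate n
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7, 0.5)
    pe <- mann_whitney_u(a, b, exact = TRUE)$p_value
    pa <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }

  expect_error(mann_whitney_u(numeric(0), 1:3), class = "sample_size_error")
})

test_that("Kruskal-Wallis matches the rank-formula oracle and Mann-Whitney", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kruskal_wallis(g)$statistic, kw_oracle(g), tolerance = 1e-9)
  expect_equal(kruskal_wallis(g)$statistic, 7.2, tolerance = 1e-9)

  set.seed(61)
  for (i in 1:15) {
    g <- lapply(1:3, function(j) sample(1:30, sample(4:9, 1), replace = TRUE))
    expect_equal(kruskal_wallis(g)$statistic, kw_oracle(g), tolerance = 1e-9)
  }

  # two groups: asymptotically equivalent to the Mann-Whitney test
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.8)
    expect_lt(abs(kruskal_wallis(list(a, b))$p_value -
                  mann_whitney_u(a, b, exact = FALSE)$p_value), 0.03)
  }

  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 4))), class = "degenerate_input")
  expect_error(kruskal_wallis(list(1:5)), class = "sample_size_error")
})

test_that("the group summary reproduces the study table structure", {
  tab <- toy_cohort_table(seed = 7)
  s <- group_summary(tab)
  expect_equal(s$groups$group, c("control", "ET0", "ET1plus", "ET2plus"))
  expect_equal(s$groups$n, c(12, 6, 5, 6))
  expect_true(all(c("ratio_S2_mean", "task_time_mean", "ftm_clinical_mean",
                    "ftm_estimated_mean") %in% names(s$groups)))
  expect_equal(nrow(s$kw), 6)
  expect_true(all(s$kw$kw_p >= 0 & s$kw$kw_p <= 1, na.rm = TRUE))
  # separated groups are detected
  expect_lt(s$kw$kw_p[s$kw$measure == "ratio_S2"], 0.01)

  # estimated-FTM column on the printed group means reproduces the worked values
  mk_row <- function(g, tt, rho, i) data.frame(
    subject_id = sprintf("%s_%d", g, i), group = g, site = "S2",
    psd_ratio = rho, task_time = tt, ftm_rater1 = 10, ftm_rater2 = 10, ftm_mean = 10
  )
  fixed <- rbind(
    do.call(rbind, lapply(1:3, function(i) mk_row("control", 12.64, 0.79, i))),
    do.call(rbind, lapply(1:3, function(i) mk_row("ET0", 20.53, 2.84, i))),
    do.call(rbind, lapply(1:3, function(i) mk_row("ET1plus", 19.82, 5.16, i))),
    do.call(rbind, lapply(1:3, function(i) mk_row("ET2plus", 26.92, 6.96, i)))
  )
  sfix <- group_summary(fixed)
  est <- sfix$groups$ftm_estimated_mean
  expect_equal(est[sfix$groups$group == "ET0"], 19.63, tolerance = 0.05 / 19.63)
  expect_equal(est[sfix$groups$group == "ET1plus"], 24.0, tolerance = 0.05 / 24)
  expect_equal(est[sfix$groups$group == "ET2plus"], 29.59, tolerance = 0.05 / 29.59)

  # identically distributed groups rarely flag differences
  set.seed(77)
  null_p <- replicate(40, {
    tabn <- toy_cohort_table(seed = sample.int(1e6, 1))
    tabn$psd_ratio <- pmax(0.05, rnorm(nrow(tabn), 3, 1))  # same distribution in all groups
    group_summary(tabn)$kw$kw_p[1 + 1]
  })
  expect_gte(mean(null_p > 0.05), 0.8)
})
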