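# Nonparametric statistical layer.  The tests themselves are the standard
# stats:: implementations; this layer fixes the conventions (min-U reporting,
# exact vs approximate switching, degenerate-input errors) and returns a
# uniform result object.

tremor_stat <- function(test_name, statistic, p_value, group_sizes, detail = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, group_sizes = group_sizes, detail = detail),
            class = "tremor_stat")
}

#' @export
print.tremor_stat <- function(x, ...) {
  stat_label <- switch(x$test_name, shapiro_wilk = "W", mann_whitney_u = "U",
                       kruskal_wallis = "H", "stat")
  cat(sprintf("%s: %s = %.4f, p = %.4g (n = %s)\n", x$test_name, stat_label,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Report-only gate for the nonparametric path: the pipeline always proceeds
#' with rank-based tests regardless of the outcome, as drawing-derived
#' features are not expected to be Gaussian.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return A `"tremor_stat"` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop_st("sample_size_error", "Shapiro-Wilk needs at least 3 values")
  if (stats::sd(values) == 0) stop_st("degenerate_input", "all values identical; normality test undefined")
  ht <- stats::shapiro.test(values)
  tremor_stat("shapiro_wilk", unname(ht$statistic), ht$p.value, n)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups.  The reported statistic is
#' `min(U_a, U_b)`, the smaller of the two U counts, so it is symmetric in
#' the group order.  Exact enumeration is used for small untied samples
#' (both groups of 8 or fewer); otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) p-values;
#'   `NULL` (default) applies the size rule above.
#' @return A `"tremor_stat"` with statistic `min(U_a, U_b)`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact = NULL) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0L || n2 == 0L) stop_st("sample_size_error", "both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  if (is.null(exact)) exact <- (n1 <= 8L && n2 <= 8L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE, alternative = "two.sided"))
  u_a <- unname(ht$statistic)  # wilcox.test W = U of the first group
  u_min <- min(u_a, n1 * n2 - u_a)
  tremor_stat("mann_whitney_u", u_min, ht$p.value, c(n1, n2),
              detail = list(u_a = u_a, u_b = n1 * n2 - u_a, exact = exact))
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return A `"tremor_stat"`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L || any(!lengths(groups))) {
    stop_st("sample_size_error", "need at least 2 non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (stats::sd(values) == 0) stop_st("degenerate_input", "all values identical across groups")
  gf <- factor(rep.int(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(values, gf)
  tremor_stat("kruskal_wallis", unname(ht$statistic), ht$p.value, lengths(groups),
              detail = list(df = unname(ht$parameter)))
}

#' Group-level summary of a cohort table
#'
#' Mirrors the study-style summary: for each group, subject counts, mean and
#' SD of the PSD ratio at each site, the task time, the clinical FTM score
#' and the sensor-estimated FTM (published model applied to each subject's
#' S2 feature pair); plus a Kruskal-Wallis p-value across groups for every
#' measure.
#'
#' @param tab A cohort table from [cohort_table()] (long format: one row per
#'   subject and site).
#' @param model Severity model used for the estimated-FTM column (default
#'   the published model).
#' @return A list of class `"cohort_summary"`: `groups` (one row per group)
#'   and `kw` (measure, Kruskal-Wallis p-value).
#' @export
group_summary <- function(tab, model = published_ftm_model()) {
  needed <- c("subject_id", "group", "site", "psd_ratio", "task_time", "ftm_mean")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) stop_st("schema_error", "cohort table lacks column(s): %s",
                                    paste(missing_cols, collapse = ", "))
  groups <- unique(tab$group)
  if (length(groups) < 2L) stop_st("sample_size_error", "need at least 2 groups to summarise")
  s2 <- tab[tab$site == "S2", ]
  s2$est_ftm <- predict(model, s2[, c("task_time", "psd_ratio")])

  measures <- list(
    ratio_S1 = function(g) tab$psd_ratio[tab$group == g & tab$site == "S1"],
    ratio_S2 = function(g) tab$psd_ratio[tab$group == g & tab$site == "S2"],
    ratio_S3 = function(g) tab$psd_ratio[tab$group == g & tab$site == "S3"],
    task_time = function(g) s2$task_time[s2$group == g],
    ftm_clinical = function(g) s2$ftm_mean[s2$group == g],
    ftm_estimated = function(g) s2$est_ftm[s2$group == g]
  )
  msd <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) c(mean = NA_real_, sd = NA_real_) else c(mean = mean(v), sd = stats::sd(v))
  }
  rows <- lapply(groups, function(g) {
    stats_g <- lapply(measures, function(f) msd(f(g)))
    row <- data.frame(group = g, n = length(unique(tab$subject_id[tab$group == g])))
    for (m in names(stats_g)) {
      row[[paste0(m, "_mean")]] <- stats_g[[m]][["mean"]]
      row[[paste0(m, "_sd")]] <- stats_g[[m]][["sd"]]
    }
    row
  })
  groups_df <- do.call(rbind, rows)

  kw <- do.call(rbind, lapply(names(measures), function(m) {
    vals <- lapply(groups, function(g) {
      v <- measures[[m]](g)
      v[is.finite(v)]
    })
    vals <- vals[lengths(vals) > 0L]
    p <- if (length(vals) >= 2L && stats::sd(unlist(vals)) > 0) kruskal_wallis(vals)$p_value else NA_real_
    data.frame(measure = m, kw_p = p, stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups_df, kw = kw), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort summary (per group, mean ± SD):\n")
  df <- x$groups
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("\nKruskal-Wallis across groups:\n")
  kw <- x$kw
  kw$kw_p <- signif(kw$kw_p, digits)
  print(kw, row.names = FALSE)
  invisible(x)
}
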