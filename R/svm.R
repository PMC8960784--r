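# Leave-one-out cross-validated SVM phenotype classification.
#
# Protocol guarantees: feature standardisation statistics are computed on
# each training fold only (no leakage into the held-out instance), the SVM
# itself is e1071/libsvm with one-vs-one multiclass, and all tie-breaks are
# deterministic.

#' Leave-one-out cross-validated SVM accuracy
#'
#' For each instance i the remaining n - 1 instances form the training set:
#' features are z-scored with the training fold's mean and SD (a constant
#' training feature divides by 1), a C-classification SVM is fitted, and
#' instance i is predicted with the same transform.  Accuracy is the
#' percentage of correctly predicted instances.
#'
#' @param features Numeric matrix or data frame (instances x features).
#' @param labels Class labels, coerced to factor.
#' @param kernel `"linear"` or `"radial"`.
#' @param cost SVM regularisation parameter C (default 1).
#' @param gamma RBF bandwidth; default `1 / ncol(features)`, the
#'   variance-scaled rule given that features are standardised.
#' @param standardize Per-fold z-scoring (default `TRUE`).
#' @return An object of class `"loocv_result"`: `accuracy` (percent),
#'   `per_fold` (true/predicted label per fold), `confusion` (k x k table),
#'   and the settings.
#' @export
loocv_accuracy <- function(features, labels, kernel = c("linear", "radial"),
                           cost = 1, gamma = NULL, standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_st("data_error", "features must be finite")
  y <- factor(labels)
  n <- nrow(X)
  if (length(y) != n) stop_st("schema_error", "labels must match the number of feature rows")
  if (nlevels(y) < 2L) stop_st("invalid_parameter", "need at least 2 classes")
  sizes <- table(y)
  if (any(sizes == 1L)) {
    warning(sprintf("class(es) with a single member (%s): their folds train without that class",
                    paste(names(sizes)[sizes == 1L], collapse = ", ")))
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    Xte <- X[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sd_tr <- apply(Xtr, 2L, stats::sd)
      sd_tr[sd_tr == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sd_tr, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sd_tr, "/")
    }
    if (nlevels(ytr) < 2L) {
      # degenerate fold: the training set holds a single class
      pred[i] <- levels(ytr)
    } else {
      fit <- e1071::svm(Xtr, ytr, type = "C-classification", kernel = kernel,
                        cost = cost, gamma = gamma, scale = FALSE)
      pred[i] <- as.character(predict(fit, Xte))
    }
  }
  pred <- factor(pred, levels = levels(y))
  confusion <- table(true = y, predicted = pred)
  structure(list(
    accuracy = 100 * mean(pred == y),
    per_fold = data.frame(true = y, predicted = pred),
    confusion = confusion,
    kernel = kernel, cost = cost, gamma = gamma, n = n
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s kernel, C = %g: accuracy %.2f%% over %d folds\n",
              x$kernel, x$cost, x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Run the full phenotype classification grid
#'
#' Evaluates LOOCV SVM accuracy for every combination of feature set
#' ({task time}, {PSD ratio}, {both}), kernel (linear, RBF) and class
#' problem (2-class ET vs control; 4-class control / ET-0 / ET+1 / ET+2),
#' using the features of one sensor site.  For each feature set and class
#' problem the better kernel's accuracy is reported (ties go to the linear
#' kernel).
#'
#' @param tab Cohort table from [cohort_table()] or a data frame with
#'   columns `subject_id`, `group`, `site`, `psd_ratio`, `task_time`.
#' @param site Sensor site to classify from (default `"S2"`).
#' @param cost,gamma Passed to [loocv_accuracy()].
#' @return Data frame with one row per (feature_set, n_classes) cell:
#'   `feature_set`, `n_classes`, `best_kernel`, `accuracy_percent`,
#'   `accuracy_linear`, `accuracy_rbf`.  The per-cell `"loocv_result"`s are
#'   attached as attribute `"results"`.
#' @export
run_classification_grid <- function(tab, site = "S2", cost = 1, gamma = NULL) {
  d <- tab[tab$site == site, , drop = FALSE]
  if (!nrow(d)) stop_st("schema_error", "no rows for site %s", site)
  d$binary <- factor(ifelse(d$group == "control", "control", "ET"),
                     levels = c("control", "ET"))
  four_levels <- c("control", "ET0", "ET1plus", "ET2plus")
  have4 <- all(four_levels %in% d$group)
  if (!have4) warning("not all four groups present; skipping 4-class runs")

  feature_sets <- list(time = "task_time", psd_ratio = "psd_ratio",
                       time_psd_ratio = c("task_time", "psd_ratio"))
  rows <- list()
  results <- list()
  for (fs_name in names(feature_sets)) {
    for (k in c(2L, 4L)) {
      if (k == 4L && !have4) next
      y <- if (k == 2L) d$binary else factor(d$group, levels = four_levels)
      accs <- list()
      for (kern in c("linear", "radial")) {
        accs[[kern]] <- loocv_accuracy(d[, feature_sets[[fs_name]], drop = FALSE], y,
                                       kernel = kern, cost = cost, gamma = gamma)
      }
      best <- if (accs$radial$accuracy > accs$linear$accuracy) "radial" else "linear"
      cell <- sprintf("%s_%dclass", fs_name, k)
      results[[cell]] <- accs
      rows[[cell]] <- data.frame(
        feature_set = fs_name, n_classes = k,
        best_kernel = if (best == "radial") "rbf" else "linear",
        accuracy_percent = accs[[best]]$accuracy,
        accuracy_linear = accs$linear$accuracy,
        accuracy_rbf = accs$radial$accuracy,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
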