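#' Leave-one-subject-out folds
#'
#' One fold per subject; all of the held-out subject's recordings are
#' excluded from training and tuning in that fold.
#'
#' @param subjects Character vector of subject ids (one per recording, or
#'   unique).
#' @return List of lists with `train` (subject ids) and `test` (one
#'   subject id) per fold.
#' @export
logo_folds <- function(subjects) {
  subj <- unique(subjects)
  if (length(subj) < 3L) stop("logo_folds: need at least 3 subjects")
  lapply(subj, function(s) list(train = setdiff(subj, s), test = s))
}

#' ROC curve and C-statistic
#'
#' AUC by pair counting (ties get half credit): the probability that a
#' random positive outscores a random negative. ROC points from a
#' threshold sweep over the distinct scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels; `"oHCM"`/`TRUE`/`1` is positive.
#' @return List with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("roc_curve_auc: need both classes")
  auc <- rank_auc(scores, pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 1),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 1))
  list(roc = roc[, c("fpr", "tpr", "threshold")], auc = auc)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "oHCM"
}

#' Bootstrap confidence interval for the C-statistic
#'
#' Percentile bootstrap over subjects, resampling with replacement
#' within each class (stratified, so every resample keeps both classes).
#'
#' @param scores Subject-level scores.
#' @param labels Subject labels.
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @return Named vector `c(low, high)` (2.5 and 97.5 percentiles).
#' @export
auc_ci_bootstrap <- function(scores, labels, n_boot = 2000, seed = 1L) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("auc_ci_bootstrap: need both classes")
  ip <- which(pos); im <- which(!pos)
  with_local_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      jp <- sample(ip, length(ip), replace = TRUE)
      jm <- sample(im, length(im), replace = TRUE)
      rank_auc(c(scores[jp], scores[jm]),
               c(rep(TRUE, length(jp)), rep(FALSE, length(jm))))
    }, 1)
    stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
  })
}

#' Youden-optimal operating threshold
#'
#' The cut (midpoint between adjacent distinct scores, including the
#' degenerate all-positive and all-negative cuts) maximizing
#' sensitivity + specificity; ties resolved towards higher specificity,
#' then the higher threshold. A case is called positive when its score
#' is at or above the threshold.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (positive = `"oHCM"`/`TRUE`/`1`).
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy` and `confusion` (named vector TP, FN, TN, FP).
#' @export
youden_threshold <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("youden_threshold: need both classes")
  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (t in cuts) {
    sens <- mean(scores[pos] >= t)
    spec <- mean(scores[!pos] < t)
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
           (spec > best$spec + 1e-12 ||
              (abs(spec - best$spec) <= 1e-12 && t > best$t)))) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  tp <- sum(scores[pos] >= best$t); fn <- sum(pos) - tp
  tn <- sum(scores[!pos] < best$t); fp <- sum(!pos) - tn
  list(threshold = best$t, sensitivity = best$sens,
       specificity = best$spec,
       accuracy = (tp + tn) / length(scores),
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' Leave-one-subject-out cross-validated evaluation
#'
#' The full evaluation harness: for each subject, tune hyperparameters
#' on the remaining subjects ([tune_hyperparams()]), build the concept
#' pool, fit the 1-norm SVM, and score the held-out subject's
#' recordings. Pooled out-of-fold recording scores give the
#' recording-level ROC; subject-level scores (the mean over a subject's
#' recordings) give the headline C-statistic, bootstrap CI, Youden
#' operating point and per-subject confusion counts.
#'
#' @param bags A `ppg_bags` object from [extract_cohort_bags()].
#' @param cv List of CV settings (see [read_config()]): `sigma_grid`,
#'   `lambda_grid`, `inner_splits`, `inner_train_frac`, `pool_cap`,
#'   `tuning_pool_cap`, `n_boot`.
#' @param seed Integer master seed.
#' @param verbose Print per-fold progress.
#' @return An object of class `cv_result`.
#' @export
run_logo_cv <- function(bags, cv = list(), seed = 1L, verbose = FALSE) {
  meta <- bags$meta
  mats <- bags$bags[meta$recording_id]
  labels <- meta$label
  subjects <- meta$subject_id
  cls <- table(unique(data.frame(subjects, labels))$labels)
  if (length(cls) < 2L || any(cls < 2L)) {
    stop("run_logo_cv: need both classes with at least 2 subjects each")
  }
  sigma_grid <- cv$sigma_grid %||% c(2, 4, 8)
  lambda_grid <- cv$lambda_grid %||% c(0.01, 0.1, 1)
  inner_splits <- cv$inner_splits %||% 68L
  train_frac <- cv$inner_train_frac %||% 0.7
  pool_cap <- cv$pool_cap %||% 2000
  tuning_pool_cap <- cv$tuning_pool_cap %||% 120
  n_boot <- cv$n_boot %||% 2000

  folds <- logo_folds(subjects)
  rec_scores <- rep(NA_real_, nrow(meta))
  fold_log <- list()
  for (k in seq_along(folds)) {
    fo <- folds[[k]]
    tr <- subjects %in% fo$train
    te <- subjects == fo$test
    stopifnot(!any(tr & te))
    fold_seed <- derive_seed(seed, 1000L + k)
    res <- tryCatch({
      tune <- tune_hyperparams(mats[tr], labels[tr], subjects[tr],
                               sigma_grid = sigma_grid,
                               lambda_grid = lambda_grid,
                               inner_splits = inner_splits,
                               train_frac = train_frac,
                               pool_cap = pool_cap,
                               tuning_pool_cap = tuning_pool_cap,
                               seed = fold_seed)
      E_tr <- exp(-tune$M / tune$sigma^2)
      fit <- fit_sparse_linear(E_tr, labels[tr], tune$lambda)
      M_te <- bag_min_dists(mats[te], tune$pool)
      E_te <- exp(-M_te / tune$sigma^2)
      list(scores = as.numeric(E_te %*% fit$weights + fit$intercept),
           sigma = tune$sigma, lambda = tune$lambda)
    }, error = function(e) {
      warning("fold ", fo$test, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rec_scores[te] <- res$scores
    fold_log[[fo$test]] <- data.frame(subject_id = fo$test,
                                      sigma = res$sigma,
                                      lambda = res$lambda)
    if (verbose) {
      message(sprintf("fold %d/%d (%s): sigma=%g lambda=%g",
                      k, length(folds), fo$test, res$sigma, res$lambda))
    }
  }

  ok <- !is.na(rec_scores)
  rec_tab <- data.frame(subject_id = subjects, recording_id = meta$recording_id,
                        label = labels, ohcm_score = rec_scores,
                        stringsAsFactors = FALSE)[ok, ]
  subj_tab <- stats::aggregate(ohcm_score ~ subject_id + label, rec_tab, mean)

  rec_roc <- roc_curve_auc(rec_tab$ohcm_score, rec_tab$label)
  subj_roc <- roc_curve_auc(subj_tab$ohcm_score, subj_tab$label)
  ci <- auc_ci_bootstrap(subj_tab$ohcm_score, subj_tab$label,
                         n_boot = n_boot, seed = derive_seed(seed, 77L))
  op <- youden_threshold(subj_tab$ohcm_score, subj_tab$label)

  structure(list(recording_scores = rec_tab,
                 subject_scores = subj_tab,
                 roc_recording = rec_roc$roc,
                 roc_subject = subj_roc$roc,
                 auc_recording = rec_roc$auc,
                 c_statistic = subj_roc$auc,
                 ci_low = ci[1], ci_high = ci[2],
                 threshold = op$threshold,
                 sensitivity = op$sensitivity,
                 specificity = op$specificity,
                 accuracy = op$accuracy,
                 confusion = op$confusion,
                 fold_hyperparams = do.call(rbind, c(fold_log, make.row.names = FALSE)),
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cv_result: C-statistic %.3f (95%% CI %.3f-%.3f), ",
           "sens %.1f%%, spec %.1f%%, acc %.1f%%, ",
           "confusion TP=%d FN=%d TN=%d FP=%d>\n"),
    x$c_statistic, x$ci_low, x$ci_high, 100 * x$sensitivity,
    100 * x$specificity, 100 * x$accuracy,
    x$confusion["TP"], x$confusion["FN"], x$confusion["TN"],
    x$confusion["FP"]))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param cvres A `cv_result`.
#' @param path Output path.
#' @export
write_cv_result <- function(cvres, path) {
  obj <- unclass(cvres)
  obj$confusion <- as.list(cvres$confusion)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
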