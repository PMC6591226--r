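test_that("LOGO folds partition recordings by subject", {
  subjects <- rep(sprintf("S%02d", 1:83), times = rep(c(1, 3, 2), length.out = 83))
  folds <- logo_folds(subjects)
  expect_length(folds, 83)
  test_subjects <- vapply(folds, `[[`, "", "test")
  expect_setequal(test_subjects, unique(subjects))
  for (fo in folds[c(1, 40, 83)]) {
    expect_false(fo$test %in% fo$train)
    expect_setequal(c(fo$train, fo$test), unique(subjects))
  }
  expect_error(logo_folds(c("A", "B")), "3 subjects")
})

test_that("AUC matches brute-force pair counting", {
  pos <- c(0.9, 0.8, 0.4); neg <- c(0.7, 0.3, 0.2)
  out <- roc_curve_auc(c(pos, neg), c(rep("oHCM", 3), rep("healthy", 3)))
  # oracle: count all 9 pairs
  pairs <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  expect_equal(out$auc, sum(pairs) / 9)
  expect_equal(out$auc, 8 / 9, tolerance = 1e-12)

  # random case vs pair counting and pROC
  set.seed(42)
  s <- round(rnorm(40), 1)   # rounding forces ties
  lab <- sample(c("oHCM", "healthy"), 40, replace = TRUE, prob = c(.4, .6))
  got <- roc_curve_auc(s, lab)$auc
  p <- s[lab == "oHCM"]; n <- s[lab == "healthy"]
  oracle <- (sum(outer(p, n, ">")) + 0.5 * sum(outer(p, n, "=="))) /
    (length(p) * length(n))
  expect_equal(got, oracle, tolerance = 1e-12)
  ref <- suppressMessages(pROC::auc(pROC::roc(lab == "oHCM", s,
                                              quiet = TRUE)))
  expect_equal(got, as.numeric(ref), tolerance = 1e-12)

  # degenerate cases
  expect_equal(roc_curve_auc(c(2, 3, 0, 1),
                             c("oHCM", "oHCM", "healthy", "healthy"))$auc, 1)
  expect_equal(roc_curve_auc(rep(1, 6),
                             rep(c("oHCM", "healthy"), 3))$auc, 0.5)
  expect_error(roc_curve_auc(1:3, rep("oHCM", 3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  s <- rnorm(30)
  lab <- rep(c("oHCM", "healthy"), 15)
  a0 <- roc_curve_auc(s, lab)$auc
  for (f in list(function(x) 3 * x - 2, exp, function(x) x^3,
                 function(x) atan(x))) {
    expect_equal(roc_curve_auc(f(s), lab)$auc, a0)
  }
})

test_that("ROC points step from (0,0) to (1,1)", {
  set.seed(8)
  out <- roc_curve_auc(rnorm(25), sample(c("oHCM", "healthy"), 25, TRUE,
                                         c(.5, .5)))
  roc <- out$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("bootstrap CI brackets the point AUC and is reproducible", {
  # Perfect separation: every stratified resample is separable.
  s <- c(5, 6, 7, 0, 1, 2)
  lab <- c(rep("oHCM", 3), rep("healthy", 3))
  ci <- auc_ci_bootstrap(s, lab, n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  # Self-oracle: an independent coding of the same resampling loop.
  set.seed(10)
  s2 <- rnorm(12); lab2 <- rep(c("oHCM", "healthy"), each = 6)
  ci2 <- auc_ci_bootstrap(s2, lab2, n_boot = 500, seed = 33)
  ip <- which(lab2 == "oHCM"); im <- which(lab2 == "healthy")
  ci_ref <- ppgmiles:::with_local_seed(33, {
    aucs <- vapply(1:500, function(b) {
      jp <- sample(ip, length(ip), replace = TRUE)
      jm <- sample(im, length(im), replace = TRUE)
      p <- s2[jp]; n <- s2[jm]
      (sum(outer(p, n, ">")) + 0.5 * sum(outer(p, n, "=="))) /
        (length(p) * length(n))
    }, 1)
    quantile(aucs, c(0.025, 0.975), names = FALSE)
  })
  expect_equal(unname(ci2), ci_ref, tolerance = 1e-12)

  a <- roc_curve_auc(s2, lab2)$auc
  expect_lte(ci2[1], a + 1e-12)
  expect_gte(ci2[2], a - 1e-12)
})

test_that("Youden threshold follows the documented tie-breaks", {
  pos <- c(0.9, 0.8, 0.6); neg <- c(0.7, 0.3, 0.2)
  lab <- c(rep("oHCM", 3), rep("healthy", 3))
  # Brute-force oracle over all cut midpoints.
  s <- c(pos, neg)
  cuts <- sort(unique(s))
  cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2,
            cuts[length(cuts)] + 1)
  j <- vapply(cuts, function(t) mean(pos >= t) + mean(neg < t), 1)
  expect_equal(max(j), 5 / 3, tolerance = 1e-12)
  expect_equal(sum(abs(j - max(j)) < 1e-12), 2)  # two tied cut regions

  out <- youden_threshold(s, lab)
  # tie-break: the higher-specificity region (sens 2/3, spec 1)
  expect_equal(out$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(out$specificity, 1)
  expect_equal(unname(out$confusion), c(2L, 1L, 3L, 0L))

  # separable scores: sens = spec = 1
  out2 <- youden_threshold(c(5, 6, 0, 1), c("oHCM", "oHCM",
                                            "healthy", "healthy"))
  expect_equal(out2$sensitivity, 1)
  expect_equal(out2$specificity, 1)
  expect_equal(out2$accuracy, 1)

  # a threshold below every score gives sens 1, spec 0
  all_scores <- c(1, 2, 3, 4)
  lab3 <- c("oHCM", "healthy", "oHCM", "healthy")
  t_low <- min(all_scores) - 1
  expect_equal(mean(all_scores[c(1, 3)] >= t_low), 1)
  expect_equal(mean(all_scores[c(2, 4)] < t_low), 0)
})

test_that("LOGO cross-validation separates a separable cohort w/o leakage", {
  set.seed(50)
  n_sub <- 10
  subjects <- rep(sprintf("S%d", 1:n_sub), each = 2)
  labels <- rep(rep(c("oHCM", "healthy"), each = 2), length.out = 2 * n_sub)
  labels <- rep(c("oHCM", "healthy"), each = 2)[rep(1:2, n_sub)]
  labels <- ifelse(as.integer(sub("S", "", subjects)) <= 5, "oHCM", "healthy")
  # Coherent bags: a subject prototype plus small beat-level noise, the
  # way real beats cluster tightly within a recording.
  protos <- lapply(unique(subjects), function(s) rnorm(42, sd = 0.2))
  names(protos) <- unique(subjects)
  mats <- lapply(seq_along(subjects), function(i) {
    shift <- if (labels[i] == "oHCM") 4 else 0
    base <- protos[[subjects[i]]] + shift
    t(replicate(30, base + rnorm(42, sd = 0.3)))
  })
  ids <- sprintf("r%02d", seq_along(mats))
  bags <- list(); meta <- list()
  for (i in seq_along(mats)) {
    bags[[ids[i]]] <- mats[[i]]
    meta[[i]] <- data.frame(subject_id = subjects[i], recording_id = ids[i],
                            label = labels[i], n_beats = 30,
                            stringsAsFactors = FALSE)
  }
  bb <- structure(list(bags = bags, meta = do.call(rbind, meta)),
                  class = "ppg_bags")
  cvs <- list(sigma_grid = c(2, 8), lambda_grid = c(0.05, 0.5),
              inner_splits = 6, pool_cap = 400, tuning_pool_cap = 100,
              n_boot = 200)
  res <- run_logo_cv(bb, cvs, seed = 9)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$recording_scores), 20)  # every recording scored once
  expect_false(anyDuplicated(res$recording_scores$recording_id) > 0)
  expect_equal(res$c_statistic, 1)
  expect_equal(unname(res$confusion[c("TP", "TN")]), c(5L, 5L))
  expect_true(res$ci_low <= res$c_statistic &&
                res$c_statistic <= res$ci_high)
  # determinism
  res2 <- run_logo_cv(bb, cvs, seed = 9)
  expect_identical(res$recording_scores$ohcm_score,
                   res2$recording_scores$ohcm_score)

  # leakage guard: no held-out subject inside any training fold
  folds <- logo_folds(subjects)
  for (fo in folds) expect_false(fo$test %in% fo$train)
})
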