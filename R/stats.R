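#' Per-subject feature summaries
#'
#' Collapses beat-level feature bags to one 42-entry summary per subject:
#' the median of each feature over all qualified beats of all of the
#' subject's recordings. Subjects are the statistical unit of the group
#' comparison; summarising first avoids pseudo-replication across the
#' hundreds of (highly dependent) beats a subject contributes.
#'
#' @param bags A `ppg_bags` object from [extract_cohort_bags()].
#' @return A list with `summaries` (subjects x 42 matrix) and `labels`
#'   (named character vector of class labels per subject).
#' @export
subject_feature_summary <- function(bags) {
  meta <- bags$meta
  subjects <- unique(meta$subject_id)
  out <- matrix(NA_real_, length(subjects), 42L,
                dimnames = list(subjects, feature_ids()))
  labels <- stats::setNames(character(length(subjects)), subjects)
  keep <- logical(length(subjects))
  for (i in seq_along(subjects)) {
    rids <- meta$recording_id[meta$subject_id == subjects[i]]
    mats <- bags$bags[rids]
    mats <- mats[!vapply(mats, is.null, TRUE)]
    if (!length(mats)) {
      warning("subject ", subjects[i], " has no usable recording; excluded")
      next
    }
    pooled <- do.call(rbind, mats)
    out[i, ] <- apply(pooled, 2, stats::median)
    labels[i] <- meta$label[meta$subject_id == subjects[i]][1]
    keep[i] <- TRUE
  }
  list(summaries = out[keep, , drop = FALSE], labels = labels[keep])
}

# Mann-Whitney U statistic (number of (g1, g2) pairs with g1 > g2, ties
# counted 1/2) and the two-sided p-value: exact by complete enumeration
# of all label assignments when both groups have <= `exact_max` members
# (valid with ties), otherwise the normal approximation with tie
# correction.
mann_whitney <- function(g1, g2, exact_max = 8L) {
  n1 <- length(g1); n2 <- length(g2)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_of(g1, g2)
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(g1, g2)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    pooled <- c(g1, g2)
    r <- rank(pooled)
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)   # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(u = u, p = p)
}

#' Compare the 42 features between cohorts
#'
#' Two-sided Mann--Whitney test per feature on subject-level summaries
#' (exact enumeration when both groups have at most 8 subjects, normal
#' approximation with tie correction otherwise), Cliff's delta as the
#' effect size (positive when the oHCM group tends higher), and
#' Bonferroni correction over exactly 42 tests.
#'
#' @param healthy_summ,ohcm_summ Subject x 42 matrices (rows are
#'   subjects) as produced by [subject_feature_summary()].
#' @param alpha Significance level after correction (default 0.05).
#' @return A data.frame of class `feature_comparison` with columns
#'   `feature_id`, `name`, `median_healthy`, `median_ohcm`, `delta`,
#'   `raw_p`, `adjusted_p`, `significant`.
#' @export
compare_feature_groups <- function(healthy_summ, ohcm_summ, alpha = 0.05) {
  stopifnot(ncol(healthy_summ) == 42L, ncol(ohcm_summ) == 42L)
  if (nrow(healthy_summ) < 2L || nrow(ohcm_summ) < 2L) {
    stop("compare_feature_groups: need at least 2 subjects per group")
  }
  cat42 <- feature_catalog()
  n1 <- nrow(ohcm_summ); n2 <- nrow(healthy_summ)
  rows <- lapply(seq_len(42L), function(j) {
    o <- ohcm_summ[, j]; h <- healthy_summ[, j]
    if (stats::sd(c(o, h)) == 0) {
      # constant in both groups: no evidence either way
      return(data.frame(feature_id = cat42$id[j], name = cat42$name[j],
                        median_healthy = stats::median(h),
                        median_ohcm = stats::median(o),
                        delta = 0, raw_p = 1, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(o, h)
    gt <- sum(outer(o, h, ">")); lt <- sum(outer(o, h, "<"))
    data.frame(feature_id = cat42$id[j], name = cat42$name[j],
               median_healthy = stats::median(h),
               median_ohcm = stats::median(o),
               delta = (gt - lt) / (n1 * n2),
               raw_p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = "bonferroni", n = 42L)
  out$significant <- out$adjusted_p < alpha
  class(out) <- c("feature_comparison", "data.frame")
  out
}

#' Volcano table of feature comparisons
#'
#' One row per feature with effect magnitude |delta|, -log10 adjusted p,
#' and the significance flag, sorted by adjusted p (the tabular form of
#' the usual volcano display; plotting is presentation on top of this).
#'
#' @param comparisons A `feature_comparison` data.frame.
#' @return A data.frame with columns `feature_id`, `name`,
#'   `effect_magnitude`, `minus_log10_adj_p`, `significant`.
#' @export
volcano_table <- function(comparisons) {
  out <- data.frame(feature_id = comparisons$feature_id,
                    name = comparisons$name,
                    effect_magnitude = abs(comparisons$delta),
                    minus_log10_adj_p = -log10(comparisons$adjusted_p),
                    significant = comparisons$significant,
                    stringsAsFactors = FALSE)
  out[order(comparisons$adjusted_p, -out$effect_magnitude), ]
}
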