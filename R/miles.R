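#' Build a MILES concept-instance pool
#'
#' Fits per-feature standardization (mean/SD) on all training beats and
#' selects the concept instances the embedding is computed against. When
#' the training set holds at most `pool_cap` instances the pool is all of
#' them (canonical MILES); otherwise a seeded uniform subsample of
#' `pool_cap` instances stratified by bag label (equal allocation per
#' class, topped up from the other class when one is short).
#'
#' @param bags List of instance matrices (beats x 42), one per training
#'   recording.
#' @param labels Character vector of bag labels (`"healthy"`/`"oHCM"`),
#'   one per bag.
#' @param pool_cap Maximum pool size (default 2000).
#' @param seed Integer seed for the subsample.
#' @return An object of class `concept_pool`: `concepts` (standardized
#'   pool matrix), `center`, `scale`, `origin_bag` (index of the source
#'   bag per concept), `catalog_version`.
#' @export
build_concept_pool <- function(bags, labels = NULL, pool_cap = 2000,
                               seed = 1L) {
  if (!length(bags)) stop("build_concept_pool: empty training set")
  if (length(bags) < 2L) stop("build_concept_pool: need at least 2 bags")
  all_x <- do.call(rbind, bags)
  origin <- rep(seq_along(bags), vapply(bags, nrow, 1L))
  ctr <- colMeans(all_x)
  scl <- apply(all_x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(all_x, 2, ctr), 2, scl, "/")

  n_tot <- nrow(z)
  if (n_tot <= pool_cap) {
    idx <- seq_len(n_tot)
  } else if (is.null(labels)) {
    idx <- with_local_seed(seed, sort(sample(n_tot, pool_cap)))
  } else {
    inst_lab <- labels[origin]
    classes <- unique(inst_lab)
    idx <- with_local_seed(seed, {
      per <- floor(pool_cap / length(classes))
      picked <- list()
      short <- 0L
      for (cl in classes) {
        ii <- which(inst_lab == cl)
        take <- min(per, length(ii))
        short <- short + per - take
        picked[[cl]] <- if (take == length(ii)) ii else sample(ii, take)
      }
      extra <- pool_cap - length(unlist(picked))
      if (extra > 0) {
        rest <- setdiff(seq_len(n_tot), unlist(picked))
        picked$extra <- sample(rest, min(extra, length(rest)))
      }
      sort(unlist(picked, use.names = FALSE))
    })
  }
  structure(list(concepts = z[idx, , drop = FALSE],
                 center = ctr, scale = scl,
                 origin_bag = origin[idx],
                 catalog_version = "ppgmiles-42-v1"),
            class = "concept_pool")
}

# Minimum squared standardized Euclidean distance from each bag to each
# concept: rows = bags, cols = concepts. The per-(bag, concept) minimum
# over instances is all the MILES embedding needs for any kernel width,
# since max_j exp(-d_j^2/s^2) = exp(-min_j d_j^2 / s^2).
bag_min_dists <- function(bags, pool) {
  C <- pool$concepts
  tC <- t(C)
  c2 <- colSums(tC^2)
  out <- matrix(NA_real_, length(bags), nrow(C))
  for (i in seq_along(bags)) {
    z <- sweep(sweep(bags[[i]], 2, pool$center), 2, pool$scale, "/")
    A <- z %*% tC
    out[i, ] <- colmin_shift(A, rowSums(z^2)) + c2
  }
  pmax(out, 0)
}

#' Embed one bag into concept-similarity space
#'
#' The MILES embedding: coordinate k is the maximum over the bag's
#' instances of `exp(-d^2/sigma^2)` where `d` is Euclidean distance to
#' concept k on features standardized with the pool's parameters. Every
#' coordinate lies in (0, 1] and is non-decreasing in `sigma`.
#'
#' @param bag Instance matrix (beats x 42).
#' @param pool A [build_concept_pool()] result.
#' @param sigma Kernel width in standardized-feature distance units.
#' @return Numeric vector, one coordinate per concept.
#' @export
embed_bag <- function(bag, pool, sigma) {
  if (!is_pos_num(sigma)) stop("embed_bag: sigma must be a positive number")
  if (!nrow(bag)) stop("embed_bag: empty bag")
  M <- bag_min_dists(list(bag), pool)
  exp(-M[1, ] / sigma^2)
}

#' Fit the sparse linear (1-norm SVM) classifier
#'
#' Minimizes mean hinge loss plus `lambda * ||w||_1` over embedded
#' recordings -- the MILES decision stage. The problem is a linear
#' program solved exactly by revised simplex, so refits are
#' deterministic and independent of starting point up to solver
#' tolerance.
#'
#' @param embeddings Matrix (bags x concepts).
#' @param labels Bag labels; `"oHCM"` (or `1`) is the positive class.
#' @param lambda Positive L1 penalty.
#' @param warm_basis Optional basis from a previous fit for warm start.
#' @return List with `weights`, `intercept`, `objective`, `basis`,
#'   `status`.
#' @export
fit_sparse_linear <- function(embeddings, labels, lambda, warm_basis = NULL) {
  if (!is_pos_num(lambda)) stop("fit_sparse_linear: lambda must be positive")
  y <- label_sign(labels)
  if (length(unique(y)) < 2L) {
    stop("fit_sparse_linear: degenerate training set (single class)")
  }
  fit <- lp_hinge_l1(as.matrix(embeddings), y, lambda,
                     basis0 = warm_basis)
  if (!identical(fit$status, "optimal")) {
    warning("fit_sparse_linear: solver status ", fit$status)
  }
  fit
}

label_sign <- function(labels) {
  if (is.numeric(labels)) {
    y <- ifelse(labels > 0, 1, -1)
  } else {
    y <- ifelse(labels == "oHCM", 1, -1)
  }
  as.numeric(y)
}

#' Fit a full MILES model
#'
#' Pool construction, embedding and sparse linear fit in one call.
#'
#' @param bags List of instance matrices (one per recording).
#' @param labels Bag labels (`"healthy"`/`"oHCM"`).
#' @param sigma Kernel width (standardized units).
#' @param lambda L1 penalty.
#' @param pool_cap Concept pool cap.
#' @param seed Integer seed (pool subsampling).
#' @return An object of class `miles_model`.
#' @export
miles_fit <- function(bags, labels, sigma, lambda, pool_cap = 2000,
                      seed = 1L) {
  pool <- build_concept_pool(bags, labels, pool_cap = pool_cap, seed = seed)
  M <- bag_min_dists(bags, pool)
  E <- exp(-M / sigma^2)
  fit <- fit_sparse_linear(E, labels, lambda)
  structure(list(pool = pool, sigma = sigma, lambda = lambda,
                 weights = as.numeric(fit$weights),
                 intercept = fit$intercept,
                 objective = fit$objective),
            class = "miles_model")
}

#' @export
print.miles_model <- function(x, ...) {
  cat(sprintf(
    "<miles_model: %d concepts, sigma=%g, lambda=%g, %d active weights>\n",
    nrow(x$pool$concepts), x$sigma, x$lambda, sum(x$weights != 0)))
  invisible(x)
}

#' Score a recording with a MILES model
#'
#' The oHCM score: `weights . embedding + intercept`. Higher means more
#' oHCM-like; the score is a margin value, not a calibrated probability.
#'
#' @param bag Instance matrix of the recording's qualified beats.
#' @param model A [miles_fit()] model.
#' @return A single numeric score.
#' @export
score_recording <- function(bag, model) {
  e <- embed_bag(bag, model$pool, model$sigma)
  sum(model$weights * e) + model$intercept
}

#' Tune MILES hyperparameters by repeated subject-level splits
#'
#' Inner model selection: `inner_splits` seeded random subject-level
#' splits (default 68 splits, 70% of subjects to the training side). In
#' each split a model is trained on the training side and its AUC
#' measured on the held-out side; the grid point with the best mean AUC
#' wins, ties going to the smallest `sigma`, then the largest `lambda`
#' (the most regularized of the equally good candidates).
#'
#' For efficiency the candidate pool and standardization are built once
#' from all supplied bags and each split embeds against the subset of
#' concepts originating from its training bags (capped at
#' `tuning_pool_cap`); distances are reused across the whole grid.
#'
#' @param bags List of instance matrices.
#' @param labels Bag labels.
#' @param subjects Subject id per bag (split unit).
#' @param sigma_grid,lambda_grid Numeric grids.
#' @param inner_splits Number of random splits (default 68).
#' @param train_frac Fraction of subjects on the training side (default
#'   0.7; set 0.3 to honour a literal 70% testing / 30% training split).
#' @param pool_cap Candidate pool cap (default 2000).
#' @param tuning_pool_cap Per-split concept cap during tuning (default
#'   120).
#' @param seed Integer seed.
#' @param pool,M Optional precomputed [build_concept_pool()] result and
#'   its [bag_min_dists] matrix (reused by the cross-validation driver).
#' @return List with `sigma`, `lambda`, `auc_table` (mean inner AUC per
#'   grid point), `pool`, `M`.
#' @export
tune_hyperparams <- function(bags, labels, subjects,
                             sigma_grid = c(2, 4, 8),
                             lambda_grid = c(0.01, 0.1, 1),
                             inner_splits = 68L,
                             train_frac = 0.7,
                             pool_cap = 2000,
                             tuning_pool_cap = 120,
                             seed = 1L,
                             pool = NULL, M = NULL) {
  stopifnot(length(bags) == length(labels),
            length(bags) == length(subjects))
  if (!length(sigma_grid) || !length(lambda_grid)) {
    stop("tune_hyperparams: empty hyperparameter grid")
  }
  subj <- unique(subjects)
  if (length(subj) < 4L) stop("tune_hyperparams: need at least 4 subjects")
  if (is.null(pool)) {
    pool <- build_concept_pool(bags, labels, pool_cap = pool_cap,
                               seed = derive_seed(seed, 1L))
  }
  if (is.null(M)) M <- bag_min_dists(bags, pool)
  y <- label_sign(labels)
  lam_order <- order(lambda_grid, decreasing = TRUE)  # warm start path

  auc_sum <- matrix(0, length(sigma_grid), length(lambda_grid))
  auc_n <- 0L
  for (s in seq_len(inner_splits)) {
    split <- with_local_seed(derive_seed(seed, 100L + s), {
      tr <- sample(subj, max(2L, round(train_frac * length(subj))))
      tr
    })
    tr_bag <- subjects %in% split
    if (length(unique(y[tr_bag])) < 2L || length(unique(y[!tr_bag])) < 2L) {
      next   # split left a side single-class; skip it
    }
    cols <- which(pool$origin_bag %in% which(tr_bag))
    if (length(cols) > tuning_pool_cap) {
      cols <- with_local_seed(derive_seed(seed, 200L + s),
                              sort(sample(cols, tuning_pool_cap)))
    }
    if (!length(cols)) next
    auc_n <- auc_n + 1L
    for (si in seq_along(sigma_grid)) {
      E <- exp(-M[, cols, drop = FALSE] / sigma_grid[si]^2)
      basis <- NULL
      for (li in lam_order) {
        fit <- lp_hinge_l1(E[tr_bag, , drop = FALSE], y[tr_bag],
                           lambda_grid[li], basis0 = basis)
        basis <- fit$basis
        sc <- E[!tr_bag, , drop = FALSE] %*% fit$weights + fit$intercept
        auc_sum[si, li] <- auc_sum[si, li] +
          rank_auc(as.numeric(sc), y[!tr_bag] > 0)
      }
    }
  }
  if (auc_n == 0L) {
    # Degenerate cohorts (too few subjects for two-class inner test
    # sides) cannot rank the grid; fall back to the grid midpoint.
    warning("tune_hyperparams: no usable inner split; ",
            "falling back to the grid midpoint")
    sg <- sort(sigma_grid); lg <- sort(lambda_grid)
    return(list(sigma = sg[ceiling(length(sg) / 2)],
                lambda = lg[ceiling(length(lg) / 2)],
                auc_table = NULL, pool = pool, M = M))
  }
  auc_mean <- auc_sum / auc_n
  # best mean AUC; ties -> smallest sigma, then largest lambda
  best <- -Inf; bi <- 1L; bj <- 1L
  for (si in order(sigma_grid)) {
    for (li in order(lambda_grid, decreasing = TRUE)) {
      if (auc_mean[si, li] > best + 1e-12) {
        best <- auc_mean[si, li]; bi <- si; bj <- li
      }
    }
  }
  auc_table <- expand.grid(sigma = sigma_grid, lambda = lambda_grid)
  auc_table$mean_auc <- as.numeric(auc_mean)
  list(sigma = sigma_grid[bi], lambda = lambda_grid[bj],
       auc_table = auc_table, pool = pool, M = M)
}

# AUC by the rank formula (average ranks give ties the conventional 1/2
# credit).
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize / load a MILES model as JSON
#'
#' @param model A `miles_model`.
#' @param path Output (input) file path.
#' @return `read_miles_model` returns the restored `miles_model`.
#' @export
write_miles_model <- function(model, path) {
  obj <- list(catalog_version = model$pool$catalog_version,
              sigma = model$sigma, lambda = model$lambda,
              weights = model$weights, intercept = model$intercept,
              center = as.numeric(model$pool$center),
              scale = as.numeric(model$pool$scale),
              origin_bag = model$pool$origin_bag,
              concepts = model$pool$concepts)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_miles_model
#' @export
read_miles_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pool <- structure(list(concepts = as.matrix(obj$concepts),
                         center = obj$center, scale = obj$scale,
                         origin_bag = obj$origin_bag,
                         catalog_version = obj$catalog_version),
                    class = "concept_pool")
  colnames(pool$concepts) <- feature_ids()
  structure(list(pool = pool, sigma = obj$sigma, lambda = obj$lambda,
                 weights = obj$weights, intercept = obj$intercept,
                 objective = NA_real_),
            class = "miles_model")
}
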