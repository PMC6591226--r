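test_that("concept pool takes all instances below the cap", {
  bags <- random_bags(3, 10, seed = 1)
  pool <- build_concept_pool(bags, rep("healthy", 3), pool_cap = 1000,
                             seed = 1)
  expect_equal(nrow(pool$concepts), 30)
  expect_equal(length(pool$origin_bag), 30)
  # standardization comes from the training instances
  allx <- do.call(rbind, bags)
  expect_equal(pool$center, colMeans(allx))
})

test_that("oversized training sets are subsampled stratified by label", {
  bags <- random_bags(40, 60, seed = 2)   # 2400 instances
  labels <- rep(c("healthy", "oHCM"), each = 20)
  pool <- build_concept_pool(bags, labels, pool_cap = 1000, seed = 3)
  expect_equal(nrow(pool$concepts), 1000)
  lab_of <- labels[pool$origin_bag]
  expect_equal(sum(lab_of == "healthy"), 500)
  expect_equal(sum(lab_of == "oHCM"), 500)
  pool2 <- build_concept_pool(bags, labels, pool_cap = 1000, seed = 3)
  expect_identical(pool$concepts, pool2$concepts)
  # One-sided class shortage is topped up from the other class.
  labs2 <- c(rep("healthy", 38), rep("oHCM", 2))
  pool3 <- build_concept_pool(bags, labs2, pool_cap = 1000, seed = 4)
  expect_equal(nrow(pool3$concepts), 1000)
  expect_equal(sum(labs2[pool3$origin_bag] == "oHCM"), 120)
})

test_that("embedding is exact on constructed distances", {
  # A pool whose standardization is identity: centred unit-variance data.
  set.seed(5)
  base <- matrix(rnorm(400 * 42), 400, 42)
  base <- scale(base)
  bags <- list(base[1:200, ], base[201:400, ])
  pool <- build_concept_pool(bags, c("healthy", "oHCM"), pool_cap = 4000)
  # Bag containing a concept instance itself: coordinate 1.
  e <- embed_bag(bags[[1]], pool, sigma = 2)
  expect_equal(max(e), 1, tolerance = 1e-12)
  expect_true(all(e > 0 & e <= 1))

  # Hand-built distances 1 and 2 from one concept, sigma 1 -> e^-1.
  c1 <- pool$concepts[1, ] * pool$scale + pool$center  # de-standardized
  u <- rep(0, 42); u[1] <- 1
  bag <- rbind(c1 + u * pool$scale[1], c1 + 2 * u * pool$scale[1])
  e2 <- embed_bag(bag, pool, sigma = 1)
  expect_equal(unname(e2[1]), exp(-1), tolerance = 1e-9)

  # sigma -> large: all coordinates -> 1; monotone in sigma.
  e_small <- embed_bag(bags[[2]], pool, 1)
  e_mid <- embed_bag(bags[[2]], pool, 4)
  e_big <- embed_bag(bags[[2]], pool, 1e6)
  expect_true(all(e_big > 1 - 1e-6))
  expect_true(all(e_mid >= e_small - 1e-12))

  # Bag permutation invariance, and duplication invariance of max.
  perm <- sample(nrow(bags[[1]]))
  expect_equal(embed_bag(bags[[1]][perm, ], pool, 2),
               embed_bag(bags[[1]], pool, 2))
  expect_equal(embed_bag(rbind(bag, bag), pool, 1), e2)

  expect_error(embed_bag(bags[[1]], pool, 0), "sigma")
})

test_that("sparse linear fit solves the hinge+L1 program exactly", {
  # Separable 1-D embeddings.
  E <- matrix(c(1, 1, 0, 0), 4, 1)
  fit <- fit_sparse_linear(E, c("oHCM", "oHCM", "healthy", "healthy"), 0.1)
  sc <- E %*% fit$weights + fit$intercept
  expect_true(all(sign(sc) == c(1, 1, -1, -1)))

  # 4 bags, 2 concept coordinates: match a brute-force grid oracle.
  E2 <- matrix(c(0.9, 0.2, 0.8, 0.3, 0.2, 0.7, 0.1, 0.9), 4, 2,
               byrow = TRUE)
  y <- c(1, 1, -1, -1)
  lab <- c("oHCM", "oHCM", "healthy", "healthy")
  fit2 <- fit_sparse_linear(E2, lab, 0.1)
  objective <- function(w1, w2, b) {
    mean(pmax(0, 1 - y * (E2[, 1] * w1 + E2[, 2] * w2 + b))) +
      0.1 * (abs(w1) + abs(w2))
  }
  # coarse-to-fine grid over [-5,5]^2 x intercept, final step 0.01
  grid_best <- function(w1r, w2r, br, step) {
    best <- c(Inf, NA, NA, NA)
    for (w1 in seq(w1r[1], w1r[2], step))
      for (w2 in seq(w2r[1], w2r[2], step)) {
        o <- vapply(seq(br[1], br[2], step),
                    function(b) objective(w1, w2, b), 1)
        i <- which.min(o)
        if (o[i] < best[1]) best <- c(o[i], w1, w2, seq(br[1], br[2], step)[i])
      }
    best
  }
  g1 <- grid_best(c(-5, 5), c(-5, 5), c(-5, 5), 0.1)
  g2 <- grid_best(g1[2] + c(-0.1, 0.1), g1[3] + c(-0.1, 0.1),
                  g1[4] + c(-0.1, 0.1), 0.01)
  expect_lt(abs(fit2$objective - g2[1]), 1e-2)

  # Huge penalty zeroes the weights; decision is the intercept sign.
  fit3 <- fit_sparse_linear(E2, lab, 1e4)
  expect_true(all(fit3$weights == 0))

  expect_error(fit_sparse_linear(E2, rep("oHCM", 4), 0.1), "single class")
  expect_error(fit_sparse_linear(E2, lab, -1), "lambda")
})

test_that("refits reach the same objective from different starts", {
  set.seed(11)
  E <- matrix(runif(60 * 25), 60, 25)
  lab <- rep(c("oHCM", "healthy"), 30)
  f1 <- fit_sparse_linear(E, lab, 0.05)
  # a deliberately mismatched warm basis must not change the optimum
  f0 <- fit_sparse_linear(E, lab, 2)
  f2 <- fit_sparse_linear(E, lab, 0.05, warm_basis = f0$basis)
  expect_lt(abs(f1$objective - f2$objective), 1e-6)
  # column permutation: same optimum value
  perm <- sample(25)
  f3 <- fit_sparse_linear(E[, perm], lab, 0.05)
  expect_lt(abs(f1$objective - f3$objective), 1e-6)
})

test_that("scores follow the linear model and max-pooling semantics", {
  bags <- random_bags(6, 25, seed = 21)
  labels <- rep(c("oHCM", "healthy"), each = 3)
  # separate the classes cleanly in feature space
  for (i in 1:3) bags[[i]] <- bags[[i]] + 3
  model <- miles_fit(bags, labels, sigma = 4, lambda = 0.05, seed = 2)
  sc <- vapply(bags, function(b) score_recording(b, model), 1)
  expect_true(all(sc[1:3] > 0))
  expect_true(all(sc[4:6] < 0))
  # null model scores zero
  m0 <- model; m0$weights[] <- 0; m0$intercept <- 0
  expect_equal(score_recording(bags[[1]], m0), 0)
  # duplicated beats leave the score unchanged
  expect_equal(score_recording(rbind(bags[[1]], bags[[1]]), model), sc[1])
})

test_that("model JSON round trip preserves scoring", {
  bags <- random_bags(4, 15, seed = 31)
  labels <- c("oHCM", "oHCM", "healthy", "healthy")
  bags[[1]] <- bags[[1]] + 2; bags[[2]] <- bags[[2]] + 2
  model <- miles_fit(bags, labels, sigma = 2, lambda = 0.1)
  path <- tempfile(fileext = ".json")
  write_miles_model(model, path)
  m2 <- read_miles_model(path)
  for (b in bags) {
    expect_equal(score_recording(b, m2), score_recording(b, model),
                 tolerance = 1e-12)
  }
})

test_that("hyperparameter tuning selects discriminative settings", {
  # One-point grid returns that point.
  bags <- random_bags(8, 20, seed = 41)
  labels <- rep(c("oHCM", "healthy"), each = 4)
  for (i in 1:4) bags[[i]] <- bags[[i]] + 2.5
  subjects <- sprintf("S%d", 1:8)
  t1 <- tune_hyperparams(bags, labels, subjects, sigma_grid = 4,
                         lambda_grid = 0.1, inner_splits = 8, seed = 5)
  expect_equal(t1$sigma, 4)
  expect_equal(t1$lambda, 0.1)

  # {good, bad} grid: an absurd lambda cannot win against a working one.
  t2 <- tune_hyperparams(bags, labels, subjects, sigma_grid = 4,
                         lambda_grid = c(0.05, 1e6), inner_splits = 12,
                         seed = 6)
  expect_equal(t2$lambda, 0.05)

  # Determinism of the full selection.
  t3 <- tune_hyperparams(bags, labels, subjects, sigma_grid = c(2, 4),
                         lambda_grid = c(0.05, 0.5), inner_splits = 10,
                         seed = 7)
  t4 <- tune_hyperparams(bags, labels, subjects, sigma_grid = c(2, 4),
                         lambda_grid = c(0.05, 0.5), inner_splits = 10,
                         seed = 7)
  expect_identical(t3[c("sigma", "lambda", "auc_table")],
                   t4[c("sigma", "lambda", "auc_table")])

  expect_error(tune_hyperparams(bags, labels, subjects,
                                sigma_grid = numeric(0),
                                lambda_grid = 0.1), "grid")
})
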