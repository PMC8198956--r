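# Coordinate-descent LASSO, path-based size targeting, and the balanced
# leave-one-out voting procedure.

test_that("penalties at or above lambda_max zero every coefficient", {
  set.seed(61)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, letters[1:8]))
  y <- rep(c(-1, 1), each = 20)
  lmax <- lasso_lambda_max(X, y)
  for (lam in c(lmax, lmax * 1.5)) {
    fit <- lasso_fit(X, y, lam)
    expect_true(all(fit$coefficients == 0))
    expect_equal(fit$intercept, mean(y))
  }
  expect_false(all(lasso_fit(X, y, lmax * 0.9)$coefficients == 0))
})

test_that("lambda = 0 recovers the least-squares solution", {
  set.seed(67)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, letters[1:5]))
  y <- rnorm(50)
  fit <- lasso_fit(X, y, 0, tol = 1e-12)
  # normal-equations oracle on the augmented design
  A <- cbind(1, X)
  beta_ols <- as.numeric(solve(t(A) %*% A, t(A) %*% y))
  expect_equal(unname(fit$coefficients), beta_ols[-1], tolerance = 1e-6)
  expect_equal(fit$intercept, beta_ols[1], tolerance = 1e-6)
})

# columns orthonormal under the 1/n inner product and mean zero
orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * (p + 1)), n, p + 1), scale = FALSE)
  Q <- qr.Q(qr(M))[, seq_len(p), drop = FALSE]
  X <- sqrt(n) * Q
  colnames(X) <- sprintf("v%d", seq_len(p))
  X
}

test_that("orthonormal designs obey the soft-threshold identity", {
  n <- 32; p <- 6
  X <- orthonormal_design(n, p, seed = 71)
  set.seed(72)
  y <- rnorm(n)
  ols <- colMeans(X * (y - mean(y)))     # (1/n) X'y on centered response
  for (lam in c(0.02, 0.1, 0.3)) {
    fit <- lasso_fit(X, y, lam, standardize = FALSE, tol = 1e-12)
    oracle <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-10)
  }
  # |coefficient| is non-increasing in the penalty along the path
  lams <- seq(0, 0.4, by = 0.05)
  paths <- sapply(lams, function(l)
    abs(lasso_fit(X, y, l, standardize = FALSE, tol = 1e-12)$coefficients))
  expect_true(all(apply(paths, 1, function(r) all(diff(r) <= 1e-10))))
})

test_that("coordinate descent matches glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(73)
  X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, LETTERS[1:10]))
  y <- ifelse(X[, 1] - 0.5 * X[, 2] + rnorm(60) > 0, 1, -1)
  for (lam in c(0.02, 0.08, 0.2)) {
    mine <- lasso_fit(X, y, lam, tol = 1e-12)
    ref <- glmnet::glmnet(X, y, family = "gaussian", lambda = lam,
                          standardize = TRUE, thresh = 1e-14)
    expect_equal(unname(mine$coefficients),
                 as.numeric(ref$beta), tolerance = 1e-4)
    expect_equal(mine$intercept, as.numeric(ref$a0), tolerance = 1e-4)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(lasso_fit(X, rep(1, 10), 0.1), "constant")
  expect_error(lasso_fit(X, rnorm(10), -1), "non-negative")
})

test_that("a planted proportional feature is selected at k = 1", {
  recovered <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    n <- 24
    X <- matrix(rnorm(n * 15), n, 15,
                dimnames = list(NULL, sprintf("f%02d", 1:15)))
    y <- rep(c(-1, 1), each = n / 2)
    X[, 7] <- y + rnorm(n, sd = 0.1)
    sel <- select_k_features(X, y, 1)
    recovered <- recovered + identical(sel$active, "f07")
  }
  expect_equal(recovered, 50L)
})

test_that("the path reaches full support and breaks ties by feature order", {
  set.seed(79)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  y <- rnorm(40)
  cfg <- selection_config(lambda_min_ratio = 1e-5)
  sel <- select_k_features(X, y, 4, cfg)
  expect_equal(sel$achieved_k, 4)
  expect_true(sel$reached_k)
  # duplicated identical columns: the earlier column wins, deterministically
  f <- rnorm(40)
  X2 <- cbind(dup1 = f, dup2 = f, noise = rnorm(40))
  y2 <- sign(f)
  sel2 <- select_k_features(X2, y2, 1)
  sel3 <- select_k_features(X2, y2, 1)
  expect_equal(sel2$active, "dup1")
  expect_identical(sel2, sel3)
})

loo_fixture <- function(seed = 83, n_nonmet = 20, n_met = 12, p = 8,
                        perfect = FALSE) {
  set.seed(seed)
  ids <- c(sprintf("n%02d", seq_len(n_nonmet)), sprintf("m%02d", seq_len(n_met)))
  groups <- setNames(rep(c("crc_nonmet", "crc_met"), c(n_nonmet, n_met)), ids)
  X <- matrix(rnorm((n_nonmet + n_met) * p), n_nonmet + n_met, p,
              dimnames = list(ids, sprintf("f%02d", seq_len(p))))
  if (perfect) X[, 1] <- ifelse(groups == "crc_met", 1, -1)
  list(X = X, groups = groups)
}

test_that("balanced LOO runs one round per metastatic sample, disjointly", {
  fx <- loo_fixture()
  rep1 <- balanced_loocv(fx$X, fx$groups, selection_config(rng_seed = 5))
  expect_equal(rep1$n_rounds, 12)
  expect_equal(length(rep1$rounds), 12)
  for (r in rep1$rounds) {
    expect_length(intersect(r$train_ids, r$validation_ids), 0)
    expect_false(r$held_out_met %in% r$train_ids)
    expect_equal(length(r$train_ids), 2 * (12 - 1))
    expect_equal(length(r$validation_ids), 1 + (20 - 11))
  }
  # bit-identical under the same seed
  rep2 <- balanced_loocv(fx$X, fx$groups, selection_config(rng_seed = 5))
  expect_identical(rep1, rep2)
  expect_true(all(rep1$vote_histogram <= rep1$n_rounds))
  expect_error(balanced_loocv(fx$X[1:21, ], fx$groups[1:21],
                              selection_config()), "metastatic")
})

test_that("a perfectly separating marker gives unit curves and all votes", {
  fx <- loo_fixture(perfect = TRUE)
  rep_ <- balanced_loocv(fx$X, fx$groups, selection_config(rng_seed = 9))
  cur <- accuracy_recall_curves(rep_)
  expect_equal(cur$summary$mean_accuracy, rep(1, 3))
  expect_equal(cur$summary$mean_recall, rep(1, 3))
  expect_equal(unname(rep_$vote_histogram["f01", "k1"]), 12L)
})

test_that("curve means equal hand-averaged per-round values", {
  fx <- loo_fixture(seed = 89)
  rep_ <- balanced_loocv(fx$X, fx$groups,
                         selection_config(rng_seed = 2, k_values = 1:2))
  cur <- accuracy_recall_curves(rep_)
  for (k in 1:2) {
    acc <- vapply(rep_$rounds, function(r) r$per_k[[k]]$accuracy, numeric(1))
    rec <- vapply(rep_$rounds, function(r) r$per_k[[k]]$recall, numeric(1))
    expect_equal(cur$summary$mean_accuracy[cur$summary$k == k], mean(acc))
    expect_equal(cur$summary$mean_recall[cur$summary$k == k], mean(rec))
  }
})

test_that("the logistic variant also recovers a strong marker", {
  fx <- loo_fixture(seed = 97, perfect = TRUE)
  sel <- select_k_features(fx$X, ifelse(fx$groups == "crc_met", 1, -1), 1,
                           selection_config(family = "logistic"))
  expect_equal(sel$active, "f01")
})
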