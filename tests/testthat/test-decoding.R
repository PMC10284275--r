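test_that("penalty selection prefers small penalties on clean signal and large on noise", {
  set.seed(10)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y_clean <- drop(X %*% c(2, -1, 1, 0, 0, 0, 0, 0))
  grid <- lambda_grid(X, y_clean, n_lambda = 20)
  expect_identical(select_lambda(X, y_clean, grid = 5), 5)
  set.seed(11)
  lam_clean <- select_lambda(X, y_clean, grid = grid)
  expect_lte(lam_clean, grid[10])      # flexible end of the grid
  set.seed(12)
  y_noise <- rnorm(100)
  lam_noise <- select_lambda(X, y_noise, grid = lambda_grid(X, y_noise, 20))
  expect_gte(lam_noise, lambda_grid(X, y_noise, 20)[6])  # sparse end
  expect_error(select_lambda(X, rep(1, 100)), "degenerate")
})

test_that("repeated CV decoding is deterministic under a fixed seed", {
  set.seed(20)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- drop(X %*% c(1, -1, rep(0, 8))) + rnorm(60)
  cfg <- cv_config(n_folds = 5, n_repeats = 3, seed = 99)
  r1 <- cross_validated_decode(X, y, cfg)
  r2 <- cross_validated_decode(X, y, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$final_fit$coefficients, r2$final_fit$coefficients)
})

test_that("null targets give cross-validated r consistent with zero", {
  set.seed(21)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- rnorm(100)
  res <- suppressWarnings(
    cross_validated_decode(X, y, cv_config(n_repeats = 10, seed = 7)))
  ok <- !is.na(res$folds$r)
  se <- sd(res$folds$r[ok]) / sqrt(sum(ok))
  expect_lt(abs(mean(res$folds$r[ok])), 2 * se + 0.05)
})

test_that("decoding recovers a planted linear signal near its theoretical r", {
  # population R^2 = 0.25 -> expected out-of-sample r near 0.5
  set.seed(22)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10)
  w <- c(rep(sqrt(1 / 5), 5), rep(0, 5))   # signal variance 1
  y <- drop(X %*% w) + rnorm(n, sd = sqrt(3))  # total variance 4
  res <- cross_validated_decode(X, y, cv_config(n_repeats = 10, seed = 8))
  expect_gt(res$summary$mean_r, 0.5 - 0.12)
  expect_lt(res$summary$mean_r, 0.5 + 0.12)
  expect_lt(res$summary$mean_nmse, 1)
})

test_that("per-fold metrics respect their invariant ranges", {
  set.seed(23)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- drop(X %*% c(1, rep(0, 5))) + rnorm(50)
  res <- cross_validated_decode(X, y, cv_config(n_repeats = 4, seed = 3))
  expect_true(all(res$folds$r >= -1 & res$folds$r <= 1, na.rm = TRUE))
  expect_true(all(res$folds$nmse >= 0, na.rm = TRUE))
  expect_true(all(res$folds$lambda > 0))
  expect_identical(nrow(res$folds), 20L)
})

test_that("correlation map flags planted features and respects Bonferroni", {
  set.seed(24)
  X <- matrix(rnorm(100 * 6), 100, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- X[, 3]
  cm <- correlation_map(X, y)
  expect_equal(cm$r[3], 1)
  expect_true(cm$significant[3])

  y2 <- -2 * X[, 5] + rnorm(100, sd = 0.5)
  cm2 <- correlation_map(X, y2)
  expect_true(cm2$significant[5] && cm2$r[5] < 0)

  Xc <- X; Xc[, 2] <- 1
  cm3 <- correlation_map(Xc, y)
  expect_true(is.na(cm3$r[2]) && !cm3$significant[2])
})

test_that("familywise false positives stay controlled on independent noise", {
  set.seed(25)
  hits <- vapply(1:60, function(i) {
    X <- matrix(rnorm(50 * 128), 50, 128)
    any(correlation_map(X, rnorm(50))$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})
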