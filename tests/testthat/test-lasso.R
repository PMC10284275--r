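test_that("lambda = 0 reduces to ordinary least squares on a tall design", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(60)
  fit <- fit_lasso(X, y, 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(fit$coefficients - ols[-1])) / max(abs(ols[-1])), 1e-6)
  expect_lt(abs(fit$intercept - ols[1]) / max(abs(ols)), 1e-6)
})

test_that("at and above the critical penalty the solution is all-zero", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  lmax <- lasso_lambda_max(X, y)
  for (lam in c(lmax, 2 * lmax)) {
    fit <- fit_lasso(X, y, lam)
    expect_true(all(fit$coefficients == 0))
    expect_equal(unname(predict(fit, X)), rep(mean(y), 40))
  }
  expect_false(all(fit_lasso(X, y, 0.95 * lmax)$coefficients == 0))
})

test_that("the number of nonzero coefficients is non-increasing along the path", {
  set.seed(3)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(50)
  grid <- lambda_grid(X, y, n_lambda = 30)
  nz <- colSums(elevdec:::fit_lasso_path(X, y, grid)$coefficients != 0)
  expect_true(all(diff(nz) >= 0))   # grid is descending
})

test_that("coordinate descent agrees with an independent reference (glmnet)", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- drop(X %*% c(1.5, 0, -1, 0)) + rnorm(10, sd = 0.3)
  # glmnet minimizes (1/2n)||y-Xb||^2 + lam_g ||b||_1, so lam_g = lam/(2n)
  for (lam in c(0.2, 1, 4)) {
    mine <- fit_lasso(X, y, lam, tol = 1e-12)
    ref <- glmnet::glmnet(X, y, lambda = lam / (2 * nrow(X)),
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-14)
    expect_lt(max(abs(mine$coefficients - as.numeric(ref$beta))), 1e-5)
    expect_lt(abs(mine$intercept - as.numeric(ref$a0)), 1e-5)
  }
})

test_that("a planted sparse model is recovered sign-consistently at high SNR", {
  set.seed(5)
  n <- 300; p <- 20
  w_true <- c(3, -2, 2.5, -3, 2, rep(0, p - 5))
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% w_true) + rnorm(n, sd = 0.5)
  grid <- lambda_grid(X, y)
  path <- elevdec:::fit_lasso_path(X, y, grid)
  ok <- vapply(seq_along(grid), function(i) {
    w <- path$coefficients[, i]
    all(sign(w[1:5]) == sign(w_true[1:5]))  # support recovered with signs
  }, logical(1))
  expect_true(any(ok))
  lam <- select_lambda(X, y, grid = grid)
  w_sel <- fit_lasso(X, y, lam)$coefficients
  expect_true(all(which(w_true != 0) %in% which(w_sel != 0)))
})

test_that("NMSE follows the variance-normalized convention exactly", {
  y <- c(0.3, -1, 2, 0.7)
  expect_equal(nmse(y, y), 0)
  expect_equal(nmse(y, rep(mean(y), 4)), 1)
  expect_equal(nmse(c(0, 2), c(1, 1)), 1.0)   # MSE 1 / pop var 1
  expect_error(nmse(rep(1, 4), rnorm(4)), "zero variance")
  expect_error(nmse(1:3, 1:4), "length mismatch")
})

test_that("degenerate lasso inputs are rejected", {
  expect_error(fit_lasso(matrix(numeric(0), 0, 3), numeric(0), 1), "zero rows")
  expect_error(fit_lasso(matrix(c(1, NA, 2, 3), 2, 2), c(1, 2), 1),
               "non-finite")
  expect_error(fit_lasso(matrix(rnorm(4), 2, 2), c(1, 2), -1),
               "non-negative")
})
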