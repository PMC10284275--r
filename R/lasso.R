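#' Fit a LASSO linear model at a fixed penalty
#'
#' Solves \deqn{\hat w = \arg\min_w \|y - Xw - b\|^2 + \lambda \|w\|_1}
#' (unsquared sums, exactly this scaling) by cyclic coordinate descent on
#' the Gram matrix of the centered design, with the intercept `b` profiled
#' out. At `lambda = 0` on a full-column-rank tall design this is ordinary
#' least squares; at `lambda >= lasso_lambda_max(X, y)` all coefficients
#' are exactly zero and the prediction is `mean(y)`.
#'
#' Columns are used as given; standardize beforehand if the penalty should
#' act uniformly (the cross-validation driver does this per training fold).
#'
#' @param X Numeric matrix, observations x features.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param lambda Non-negative penalty.
#' @param tol Coordinate-descent convergence tolerance on the largest
#'   coefficient change per sweep.
#' @param max_sweeps Maximum full coordinate sweeps.
#' @return Object of class `lasso_model`: list with `coefficients`,
#'   `intercept`, `lambda`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-10, max_sweeps = 100000L) {
  fit <- fit_lasso_path(X, y, lambda, tol = tol, max_sweeps = max_sweeps)
  structure(list(coefficients = fit$coefficients[, 1L],
                 intercept = fit$intercepts[1L],
                 lambda = lambda),
            class = "lasso_model")
}

# Whole descending-lambda path with warm starts; shared by the CV driver.
fit_lasso_path <- function(X, y, lambdas, tol = 1e-10, max_sweeps = 100000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("zero rows in design matrix")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in inputs")
  if (any(lambdas < 0)) stop("lambda must be non-negative")
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  cty <- drop(crossprod(Xc, yc))
  W <- lasso_cd_gram(G, cty, as.numeric(lambdas), tol, as.integer(max_sweeps))
  b <- mean(y) - drop(xm %*% W)
  rownames(W) <- colnames(X)
  list(coefficients = W, intercepts = b, lambdas = lambdas)
}

#' @export
predict.lasso_model <- function(object, newx, ...) {
  drop(as.matrix(newx) %*% object$coefficients) + object$intercept
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("<lasso_model> lambda = %.4g, %d/%d nonzero coefficients\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Critical penalty above which the LASSO solution is all-zero
#'
#' Under the objective `||y - Xw - b||^2 + lambda * ||w||_1` the zero vector
#' is optimal exactly when `lambda >= 2 * max |Xc' yc|` with centered
#' `Xc`, `yc`.
#'
#' @inheritParams fit_lasso
#' @return The critical penalty value.
#' @export
lasso_lambda_max <- function(X, y) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2L, colMeans(X))
  2 * max(abs(drop(crossprod(Xc, y - mean(y)))))
}

#' Default descending log-spaced penalty grid
#'
#' 50 logarithmically spaced values from the critical penalty
#' [lasso_lambda_max()] down to `min_ratio` times it.
#'
#' @inheritParams fit_lasso
#' @param n_lambda Grid size (default 50).
#' @param min_ratio Ratio of smallest to largest penalty (default 1e-3).
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_lambda = 50L, min_ratio = 1e-3) {
  lmax <- lasso_lambda_max(X, y)
  if (lmax <= 0) stop("degenerate design: lambda_max is zero")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}
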