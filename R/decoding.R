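#' Normalized mean squared error
#'
#' Prediction MSE divided by the (population) variance of the true targets,
#' so that predicting `mean(y_true)` everywhere scores exactly 1 and a
#' perfect prediction scores 0.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
nmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  v <- mean((y_true - mean(y_true))^2)
  if (v == 0) stop("zero variance in y_true: NMSE undefined")
  mean((y_true - y_pred)^2) / v
}

# Per-column standardization parameters from a training block; constant
# columns get scale 1 (their centered values are all zero, so they can
# never enter the model).
std_params <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(X, p) sweep(sweep(X, 2L, p$center), 2L, p$scale, `/`)

#' Select the penalty by inner cross-validation
#'
#' For each penalty on the grid, computes the inner-cross-validated NMSE
#' within the training data only (standardizing with inner-training
#' statistics, so no information leaks from the held-out inner fold), and
#' returns the penalty minimizing it. The grid is descending, so exact ties
#' resolve toward the larger penalty (the sparser model).
#'
#' @param X_train,y_train Training design and response.
#' @param grid Descending penalty grid (default [lambda_grid()] of the
#'   standardized training data).
#' @param inner_folds Number of inner folds (default 5).
#' @param fold_id Optional integer vector assigning rows to inner folds;
#'   when omitted a random balanced assignment is drawn from the current
#'   RNG stream.
#' @return The selected penalty (scalar).
#' @export
select_lambda <- function(X_train, y_train, grid = NULL, inner_folds = 5L,
                          fold_id = NULL) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (sd(y_train) == 0) stop("degenerate training target: zero variance")
  if (is.null(grid)) {
    p0 <- std_params(X_train)
    grid <- lambda_grid(std_apply(X_train, p0), y_train)
  }
  if (!length(grid) || any(grid <= 0)) stop("grid must be positive and non-empty")
  grid <- sort(grid, decreasing = TRUE)
  if (length(grid) == 1L) return(grid)
  if (is.null(fold_id)) fold_id <- sample(rep_len(seq_len(inner_folds), n))
  err <- matrix(NA_real_, inner_folds, length(grid))
  for (f in seq_len(inner_folds)) {
    tr <- fold_id != f
    if (sd(y_train[tr]) == 0 || sd(y_train[!tr]) == 0) next
    p <- std_params(X_train[tr, , drop = FALSE])
    Xtr <- std_apply(X_train[tr, , drop = FALSE], p)
    Xval <- std_apply(X_train[!tr, , drop = FALSE], p)
    path <- fit_lasso_path(Xtr, y_train[tr], grid, tol = 1e-8)
    pred <- Xval %*% path$coefficients +
      matrix(path$intercepts, nrow(Xval), length(grid), byrow = TRUE)
    yv <- y_train[!tr]
    vv <- mean((yv - mean(yv))^2)
    err[f, ] <- colMeans((pred - yv)^2) / vv
  }
  cv <- colMeans(err, na.rm = TRUE)
  if (all(!is.finite(cv))) stop("inner cross-validation degenerate on all folds")
  grid[which.min(cv)]
}

#' Cross-validation configuration
#'
#' @param n_folds Outer folds (default 5).
#' @param n_repeats Number of repetitions of the whole cross-validation
#'   (default 100).
#' @param inner_folds Inner folds for penalty selection (default 5).
#' @param lambda_grid Optional fixed penalty grid; by default a fresh
#'   50-point log grid is computed from each standardized training fold.
#' @param seed Master RNG seed driving all fold shuffling; per-repeat seeds
#'   are derived deterministically so results are exactly reproducible.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 100L, inner_folds = 5L,
                      lambda_grid = NULL, seed = 1L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L, inner_folds >= 2L)
  if (!is.null(lambda_grid) && (!length(lambda_grid) || any(lambda_grid <= 0)))
    stop("lambda_grid must be strictly positive and non-empty")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 inner_folds = as.integer(inner_folds),
                 lambda_grid = lambda_grid,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Repeated nested cross-validated LASSO decoding
#'
#' For each repetition: a fresh random partition of the seconds into
#' `n_folds` folds; for each fold, features are standardized with
#' training-fold statistics, the penalty is chosen by inner
#' cross-validation on the training portion only, the model is fit on the
#' training portion and evaluated on the held-out fold by Pearson r and
#' NMSE. Folds where either the targets or the predictions are constant
#' have an undefined r; these are recorded as `NA` and excluded from the
#' aggregates (with a warning giving the count).
#'
#' @param X Numeric matrix or `feature_matrix`, seconds x features.
#' @param y Numeric target vector or `score_series`.
#' @param cfg A [cv_config()].
#' @return Object of class `decoding_result`: list with
#'   \describe{
#'     \item{folds}{data frame of per-repeat, per-fold `lambda`, `r`,
#'       `nmse`, `n_nonzero`;}
#'     \item{summary}{means and SDs of r and NMSE over all fold values, and
#'       over per-repeat means;}
#'     \item{repeat_means}{data frame of per-repeat mean r and NMSE;}
#'     \item{selection_freq}{per-feature frequency of a nonzero coefficient
#'       across all fold fits;}
#'     \item{final_fit}{a `lasso_model` refit on all data (standardized),
#'       with the penalty selected by inner CV on the full data — the
#'       coefficient support for topography-style maps.}
#'   }
#' @export
cross_validated_decode <- function(X, y, cfg = cv_config()) {
  labels <- if (inherits(X, "feature_matrix")) feature_labels(X) else NULL
  X <- unclass(as.matrix(X))
  if (inherits(y, "score_series")) y <- y$score
  y <- as.numeric(y)
  stopifnot(inherits(cfg, "cv_config"))
  n <- nrow(X)
  if (n != length(y)) stop("X rows and y length differ")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  p <- ncol(X)

  set.seed(cfg$seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_repeats)

  rows <- vector("list", cfg$n_repeats * cfg$n_folds)
  nz_count <- numeric(p)
  n_fits <- 0L
  idx <- 0L
  for (k in seq_len(cfg$n_repeats)) {
    set.seed(repeat_seeds[k])
    fold_id <- sample(rep_len(seq_len(cfg$n_folds), n))
    for (f in seq_len(cfg$n_folds)) {
      tr <- fold_id != f
      ytr <- y[tr]; yte <- y[!tr]
      sp <- std_params(X[tr, , drop = FALSE])
      Xtr <- std_apply(X[tr, , drop = FALSE], sp)
      Xte <- std_apply(X[!tr, , drop = FALSE], sp)
      grid <- if (is.null(cfg$lambda_grid)) lambda_grid(Xtr, ytr)
              else sort(cfg$lambda_grid, decreasing = TRUE)
      lam <- select_lambda(Xtr, ytr, grid = grid,
                           inner_folds = cfg$inner_folds)
      fit <- fit_lasso(Xtr, ytr, lam, tol = 1e-8)
      pred <- predict(fit, Xte)
      r <- if (sd(yte) == 0 || sd(pred) == 0) NA_real_ else cor(yte, pred)
      nm <- if (sd(yte) == 0) NA_real_ else nmse(yte, pred)
      nz <- fit$coefficients != 0
      nz_count <- nz_count + nz
      n_fits <- n_fits + 1L
      idx <- idx + 1L
      rows[[idx]] <- data.frame(rep = k, fold = f, lambda = lam, r = r,
                                nmse = nm, n_nonzero = sum(nz))
    }
  }
  folds <- do.call(rbind, rows)
  n_na <- sum(is.na(folds$r))
  if (n_na > 0L)
    warning(n_na, " fold(s) had constant targets or predictions; ",
            "their r is undefined and excluded from aggregation")
  rmeans <- aggregate(cbind(r, nmse) ~ rep, data = folds, FUN = mean,
                      na.rm = TRUE, na.action = NULL)
  summary <- list(
    mean_r = mean(folds$r, na.rm = TRUE),
    sd_r = sd(folds$r, na.rm = TRUE),
    mean_nmse = mean(folds$nmse, na.rm = TRUE),
    sd_nmse = sd(folds$nmse, na.rm = TRUE),
    mean_r_repeats = mean(rmeans$r, na.rm = TRUE),
    sd_r_repeats = sd(rmeans$r, na.rm = TRUE),
    mean_nmse_repeats = mean(rmeans$nmse, na.rm = TRUE),
    sd_nmse_repeats = sd(rmeans$nmse, na.rm = TRUE),
    n_missing_r = n_na)

  # final support: inner-CV penalty on the full standardized data
  set.seed(repeat_seeds[cfg$n_repeats] + 1L)
  spf <- std_params(X)
  Xs <- std_apply(X, spf)
  lam_full <- select_lambda(Xs, y, grid = lambda_grid(Xs, y),
                            inner_folds = cfg$inner_folds)
  final_fit <- fit_lasso(Xs, y, lam_full, tol = 1e-8)

  structure(list(folds = folds, summary = summary, repeat_means = rmeans,
                 selection_freq = nz_count / n_fits,
                 final_fit = final_fit, feature_labels = labels,
                 config = cfg),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  s <- x$summary
  cat("<decoding_result>\n")
  cat(sprintf("  %d repeats x %d folds\n",
              x$config$n_repeats, x$config$n_folds))
  cat(sprintf("  r    = %.3f +/- %.3f (fold-level), %.3f +/- %.3f (repeat means)\n",
              s$mean_r, s$sd_r, s$mean_r_repeats, s$sd_r_repeats))
  cat(sprintf("  NMSE = %.3f +/- %.3f (fold-level)\n", s$mean_nmse, s$sd_nmse))
  cat(sprintf("  final fit: %d nonzero of %d features\n",
              sum(x$final_fit$coefficients != 0),
              length(x$final_fit$coefficients)))
  invisible(x)
}

#' Univariate feature-score correlation map with Bonferroni control
#'
#' Pearson correlation and two-sided p-value between each feature column
#' and the target; a feature is flagged significant when
#' `p < alpha / n_features` (Bonferroni over all feature columns).
#' Constant feature columns get `NA` correlation and are never significant.
#'
#' @param X Numeric matrix or `feature_matrix`, seconds x features.
#' @param y Numeric target or `score_series`.
#' @param alpha Familywise significance level (default 0.05).
#' @return Data frame with columns `feature`, (`channel`, `band` when the
#'   input carries labels), `r`, `p`, `significant`.
#' @export
correlation_map <- function(X, y, alpha = 0.05) {
  labels <- if (inherits(X, "feature_matrix")) feature_labels(X) else NULL
  X <- unclass(as.matrix(X))
  if (inherits(y, "score_series")) y <- y$score
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < 3L) stop("need at least 3 seconds")
  p_feat <- ncol(X)
  r <- p <- rep(NA_real_, p_feat)
  for (j in seq_len(p_feat)) {
    xj <- X[, j]
    if (sd(xj) == 0 || sd(y) == 0) next
    ct <- cor.test(xj, y, method = "pearson")
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  out <- data.frame(feature = colnames(X) %||% paste0("V", seq_len(p_feat)),
                    r = r, p = p,
                    significant = !is.na(p) & p < alpha / p_feat,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out <- cbind(labels, out)
  out
}

#' Write the final coefficient map as CSV
#'
#' Columns `channel`, `band`, `coefficient` (on the standardized-feature
#' scale of the final fit), suitable for topography plotting.
#'
#' @param result A `decoding_result` whose features carried labels.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coefficient_map <- function(result, path) {
  stopifnot(inherits(result, "decoding_result"))
  if (is.null(result$feature_labels))
    stop("decoding result carries no channel/band labels")
  df <- cbind(result$feature_labels,
              coefficient = unname(result$final_fit$coefficients))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
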