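#' Univariate regression F statistic
#'
#' The F value of the simple linear regression of `y` on one feature,
#' `F = r^2 / (1 - r^2) * (n - 2)` with `r` the Pearson correlation. A
#' constant feature scores 0; a perfectly correlated feature returns `Inf`,
#' which sorts ahead of every finite value during selection.
#'
#' @param feature Numeric feature values over participants.
#' @param y Outcome scores (must not be constant).
#' @return A single non-negative F value (possibly `Inf`).
#' @export
f_statistic <- function(feature, y) {
  if (length(feature) != length(y)) {
    abort("`feature` and `y` must have the same length.")
  }
  if (length(y) < 3) abort("F statistic needs at least 3 observations.")
  if (sd(y) == 0) abort("`y` is constant; the outcome carries no signal.")
  .f_stats(matrix(feature, ncol = 1), y)[1]
}

# coordinate-descent controls for cross-validation paths; single-penalty
# fit_lasso() calls use a much tighter tolerance
.path_tol <- 1e-7
.path_maxit <- 2000L

# vectorised F over the columns of a feature matrix
.f_stats <- function(x, y) {
  n <- length(y)
  yc <- y - mean(y)
  xc <- sweep(x, 2, colMeans(x))
  ssx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  r2 <- ifelse(ssx > 0, sxy^2 / (ssx * sum(yc^2)), 0)
  ifelse(r2 >= 1 - 1e-12, Inf,
         pmin(r2, 1) / (1 - pmin(r2, 1)) * (n - 2))
}

#' Select the k features with the largest F values
#'
#' Ranks every feature column by its univariate F value against the outcome
#' and keeps the top `k` (50 in the reference analysis). Ties -- including
#' multiple perfectly correlated features -- are broken by canonical column
#' order. The returned rule is a plain tibble, so it can be re-applied to
#' any feature matrix sharing the schema (in particular the split-half
#' matrices).
#'
#' @param features A feature tibble (`participant_id` + numeric columns).
#' @param y Outcome scores aligned with the rows of `features`.
#' @param k Number of features to keep.
#' @param dimension Optional dimension code stored with the rule.
#' @return A tibble of class `selection_rule` with columns `dimension`,
#'   `rank`, `column`, `f_value` (non-increasing in rank).
#' @export
select_top_k <- function(features, y, k = 50, dimension = NA_character_) {
  x <- .feature_values(features)
  if (ncol(x) < k) {
    abort(sprintf("only %d feature columns available; need k = %d.",
                  ncol(x), k))
  }
  if (sd(y) == 0) abort("`y` is constant; the outcome carries no signal.")
  f <- .f_stats(x, y)
  ord <- order(-f, seq_along(f))[seq_len(k)]
  structure(
    tibble::tibble(
      dimension = dimension,
      rank = seq_len(k),
      column = colnames(x)[ord],
      f_value = f[ord]
    ),
    class = c("selection_rule", "tbl_df", "tbl", "data.frame")
  )
}

.feature_values <- function(features) {
  cols <- setdiff(names(features), "participant_id")
  as.matrix(features[, cols, drop = FALSE])
}

#' Fit and apply a feature standardiser
#'
#' `fit_scaler()` learns each selected column's mean and standard deviation
#' from the whole-data matrix; `apply_scaler()` z-scores any matrix sharing
#' the schema with those whole-data moments (the split-half matrices are
#' deliberately standardised with the whole-data scaler, not their own
#' moments). Zero-scale columns map to all zeros.
#'
#' @param features A feature tibble.
#' @param rule A `selection_rule` from [select_top_k()].
#' @return `fit_scaler()`: a tibble of class `feature_scaler` with columns
#'   `column`, `center`, `scale`. `apply_scaler()`: a numeric matrix
#'   (participants x selected columns) in rule order.
#' @export
fit_scaler <- function(features, rule) {
  x <- .selected_values(features, rule)
  structure(
    tibble::tibble(
      column = colnames(x),
      center = colMeans(x),
      scale = apply(x, 2, sd)
    ),
    class = c("feature_scaler", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(features, scaler) {
  x <- as.matrix(features[, scaler$column, drop = FALSE])
  centered <- sweep(x, 2, scaler$center)
  scl <- ifelse(scaler$scale > 0, scaler$scale, 1)
  out <- sweep(centered, 2, scl, "/")
  out[, scaler$scale == 0] <- 0
  rownames(out) <- features$participant_id
  out
}

.selected_values <- function(features, rule) {
  missing <- setdiff(rule$column, names(features))
  if (length(missing) > 0) {
    abort(sprintf("feature matrix lacks selected column %s.", missing[1]))
  }
  as.matrix(features[, rule$column, drop = FALSE])
}

#' Fit a LASSO regression at one penalty
#'
#' Minimises the un-averaged L1-penalised least-squares objective
#' `sum_i (y_i - b0 - x_i' beta)^2 + lambda * sum_j |beta_j|` by cyclic
#' coordinate descent, with an unpenalised intercept fitted on centred data.
#' At `lambda = 0` the solution is ordinary least squares; on an orthonormal
#' (centred) design each coefficient is the soft-thresholded OLS coefficient
#' `S(b_j, lambda / (2 * ||x_j||^2))`.
#'
#' @param x Numeric matrix of predictors (typically standardised).
#' @param y Outcome vector.
#' @param lambda Non-negative penalty weight (on the un-averaged objective).
#' @param tol,maxit Coordinate-descent convergence controls; `tol` is the
#'   maximum per-update change in fit, relative to the centred-outcome
#'   deviance.
#' @return A list of class `lasso_fit`: `beta` (named), `intercept`,
#'   `lambda`, `objective`.
#' @export
fit_lasso <- function(x, y, lambda, tol = 1e-15, maxit = 100000) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (lambda < 0) abort("`lambda` must be non-negative.")
  fit <- cpp_lasso_path(x, as.double(y), lambda, tol = tol, maxit = maxit)
  beta <- setNames(fit$beta[, 1], colnames(x))
  structure(
    list(beta = beta, intercept = fit$intercept[1], lambda = lambda,
         objective = lasso_objective(x, y, beta, fit$intercept[1], lambda)),
    class = "lasso_fit"
  )
}

#' @rdname fit_lasso
#' @param beta Coefficient vector.
#' @param intercept Intercept.
#' @return `lasso_objective()`: the objective value at `(beta, intercept)`.
#' @export
lasso_objective <- function(x, y, beta, intercept, lambda) {
  resid <- y - intercept - as.vector(as.matrix(x) %*% beta)
  sum(resid^2) + lambda * sum(abs(beta))
}

#' Penalty grid for LASSO tuning
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty that zeroes
#' every coefficient, `2 * max |x_c' y_c|` under the un-averaged objective)
#' down to `lambda_max * min_ratio`.
#'
#' @inheritParams fit_lasso
#' @param n_lambda Grid size.
#' @param min_ratio Ratio of the smallest to the largest grid value.
#' @return A decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(x, y, n_lambda = 100, min_ratio = 1e-4) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  lambda_max <- 2 * max(abs(crossprod(xc, yc)))
  if (lambda_max <= 0) lambda_max <- 1
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_lambda))
}

#' Assign participants to cross-validation folds
#'
#' A seeded uniform permutation into `n_folds` folds whose sizes differ by
#' at most one; no stratification.
#'
#' @param participant_ids Character vector of ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return A tibble with `participant_id` and `fold`.
#' @export
make_fold_plan <- function(participant_ids, n_folds = 5, seed = 1) {
  n <- length(participant_ids)
  if (anyDuplicated(participant_ids)) abort("duplicate participant ids.")
  if (n < n_folds) abort("fewer participants than folds.")
  set.seed(seed)
  tibble::tibble(
    participant_id = participant_ids,
    fold = sample(rep_len(seq_len(n_folds), n))
  )
}

#' Choose the penalty by cross-validated prediction error
#'
#' For every penalty in the grid, fits the training folds and accumulates
#' the out-of-fold squared error; returns the penalty minimising the mean
#' out-of-fold MSE, resolving exact ties toward the larger (more
#' parsimonious) penalty.
#'
#' @param x Standardised predictor matrix with participant row names.
#' @param y Outcome vector aligned with `x`.
#' @param plan Fold plan from [make_fold_plan()].
#' @param lambdas Penalty grid (decreasing).
#' @return A list: `lambda` (the chosen penalty), `cv` (tibble of `lambda`,
#'   `mse`).
#' @export
tune_lambda <- function(x, y, plan, lambdas) {
  if (length(lambdas) == 0) abort("empty penalty grid.")
  lambdas <- sort(lambdas, decreasing = TRUE)
  sse <- numeric(length(lambdas))
  for (f in sort(unique(plan$fold))) {
    test <- plan$fold == f
    path <- cpp_lasso_path(x[!test, , drop = FALSE], y[!test], lambdas,
                           tol = .path_tol, maxit = .path_maxit)
    pred <- x[test, , drop = FALSE] %*% path$beta +
      matrix(path$intercept, sum(test), length(lambdas), byrow = TRUE)
    sse <- sse + colSums((pred - y[test])^2)
  }
  mse <- sse / length(y)
  best <- which(mse == min(mse))[1] # grid is decreasing: first hit = largest
  list(lambda = lambdas[best],
       cv = tibble::tibble(lambda = lambdas, mse = mse))
}

#' Out-of-fold predictions for all three data variants
#'
#' For each fold, fits a LASSO at the chosen penalty on the other folds'
#' whole-data rows and predicts the held-out participants' whole, odd and
#' even feature rows with that same model, so every participant is predicted
#' exactly once per variant by a model that never saw their data.
#'
#' @param x_whole,x_odd,x_even Standardised matrices sharing row order and
#'   columns.
#' @param y Outcome vector aligned with the rows.
#' @param lambda Penalty at which the fold models are fit.
#' @param plan Fold plan covering all rows.
#' @return A tibble: `participant_id`, `dimension` (`NA`; filled by callers),
#'   `variant`, `.pred`, `fold`.
#' @export
out_of_fold_predict <- function(x_whole, x_odd, x_even, y, lambda, plan) {
  .check_schema(x_whole, x_odd, x_even)
  ids <- rownames(x_whole)
  if (!setequal(ids, plan$participant_id)) {
    abort("fold plan does not cover the feature-matrix participants.")
  }
  fold_of <- plan$fold[match(ids, plan$participant_id)]
  out <- vector("list", length(unique(fold_of)))
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    fit <- cpp_lasso_path(x_whole[!test, , drop = FALSE], y[!test], lambda,
                          tol = .path_tol, maxit = .path_maxit)
    predict_rows <- function(m) {
      as.vector(m[test, , drop = FALSE] %*% fit$beta[, 1] +
                  fit$intercept[1])
    }
    out[[f]] <- tibble::tibble(
      participant_id = rep(ids[test], 3),
      variant = rep(c("whole", "odd", "even"), each = sum(test)),
      .pred = c(predict_rows(x_whole), predict_rows(x_odd),
                predict_rows(x_even)),
      fold = f
    )
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$participant_id, .data$variant)
}

.check_schema <- function(x_whole, x_odd, x_even) {
  same <- identical(colnames(x_whole), colnames(x_odd)) &&
    identical(colnames(x_whole), colnames(x_even)) &&
    nrow(x_whole) == nrow(x_odd) && nrow(x_whole) == nrow(x_even) &&
    identical(rownames(x_whole), rownames(x_odd)) &&
    identical(rownames(x_whole), rownames(x_even))
  if (!same) abort("whole/odd/even matrices must share rows and columns.")
  invisible(TRUE)
}
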