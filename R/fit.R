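#' Fit the six facial symptom-prediction models
#'
#' For each of the six dimensions: selects the 50 features with the largest
#' univariate F value against the raw subscale score, standardises them,
#' tunes the LASSO penalty by five-fold cross-validation, and produces
#' out-of-fold predictions for the whole, odd-half and even-half feature
#' matrices (the split-half matrices are scored with the whole-data
#' selection rule and scaler).
#'
#' By default, feature selection and standardisation are fit on the full
#' whole-data matrix before cross-validation, replicating the reference
#' analysis; this leaks the held-out participants into the selection step
#' and inflates out-of-fold correlations. `strict_cv = TRUE` refits the
#' selection rule and scaler inside each training fold for a leakage-free
#' evaluation (used, for example, to verify that null cohorts produce null
#' criterion validity).
#'
#' @param features_whole,features_odd,features_even Feature tibbles from
#'   [build_feature_matrix()] or [cohort_features()], sharing participants
#'   and columns.
#' @param scores Long score tibble from [score_subscales()]; the raw
#'   subscale scores are the outcomes.
#' @param k Number of features selected per dimension.
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param strict_cv Refit selection and scaler within each training fold.
#' @param n_lambda,lambda_min_ratio Penalty-grid controls
#'   (see [lambda_grid()]).
#' @return An object of class `symptom_models`: a list with `predictions`
#'   (participant x dimension x variant out-of-fold predictions),
#'   `selection` (per-dimension whole-data selection rules), `lambda`
#'   (chosen penalty and CV error per dimension), `coefficients`
#'   (full-data refit at the chosen penalty, for interpretation), `plan`,
#'   and `settings`.
#' @export
fit_symptom_models <- function(features_whole, features_odd, features_even,
                               scores, k = 50, n_folds = 5, seed = 1,
                               strict_cv = FALSE, n_lambda = 100,
                               lambda_min_ratio = 1e-4) {
  ids <- features_whole$participant_id
  if (!identical(ids, features_odd$participant_id) ||
      !identical(ids, features_even$participant_id)) {
    abort("feature matrices must share the same participants in the same order.")
  }
  plan <- make_fold_plan(ids, n_folds = n_folds, seed = seed)
  if (strict_cv) {
    mat_whole <- .feature_values(features_whole)
    mat_odd <- .feature_values(features_odd)
    mat_even <- .feature_values(features_even)
  }

  per_dim <- purrr::map(.dim_codes, function(dim_code) {
    y <- scores |>
      dplyr::filter(.data$dimension == dim_code) |>
      dplyr::slice(match(ids, .data$participant_id))
    if (!identical(y$participant_id, ids)) {
      abort(sprintf("scores are missing participants for dimension %s.",
                    dim_code))
    }
    y <- y$raw

    rule <- select_top_k(features_whole, y, k = k, dimension = dim_code)
    scaler <- fit_scaler(features_whole, rule)
    xw <- apply_scaler(features_whole, scaler)
    xo <- apply_scaler(features_odd, scaler)
    xe <- apply_scaler(features_even, scaler)

    if (!strict_cv) {
      grid <- lambda_grid(xw, y, n_lambda = n_lambda,
                          min_ratio = lambda_min_ratio)
      tuned <- tune_lambda(xw, y, plan, grid)
      preds <- out_of_fold_predict(xw, xo, xe, y, tuned$lambda, plan)
    } else {
      strict <- .strict_cv_dimension(
        mat_whole, mat_odd, mat_even, y, ids, plan,
        k = k, n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio
      )
      tuned <- strict$tuned
      preds <- strict$preds
    }

    final <- fit_lasso(xw, y, tuned$lambda)
    list(
      preds = dplyr::mutate(preds, dimension = dim_code,
                            .after = "participant_id"),
      rule = rule,
      lambda = tibble::tibble(dimension = dim_code, lambda = tuned$lambda,
                              oof_mse = min(tuned$cv$mse)),
      coefs = tibble::tibble(
        dimension = dim_code,
        term = c("(Intercept)", names(final$beta)),
        estimate = c(final$intercept, unname(final$beta))
      )
    )
  })

  structure(
    list(
      predictions = purrr::map_dfr(per_dim, "preds") |>
        dplyr::mutate(dimension = factor(.data$dimension,
                                         levels = .dim_codes)),
      selection = purrr::map_dfr(per_dim, "rule"),
      lambda = purrr::map_dfr(per_dim, "lambda"),
      coefficients = purrr::map_dfr(per_dim, "coefs"),
      plan = plan,
      settings = list(k = k, n_folds = n_folds, seed = seed,
                      strict_cv = strict_cv, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
    ),
    class = "symptom_models"
  )
}

# leakage-free variant: selection rule, scaler and penalty scale are all
# learned inside each training fold; operates on plain matrices for speed
.strict_cv_dimension <- function(mw, mo, me, y, ids, plan, k, n_lambda,
                                 lambda_min_ratio) {
  fold_of <- plan$fold[match(ids, plan$participant_id)]
  folds <- sort(unique(fold_of))

  fold_fits <- lapply(folds, function(f) {
    train <- fold_of != f
    xtr <- mw[train, , drop = FALSE]
    f_vals <- .f_stats(xtr, y[train])
    sel <- order(-f_vals, seq_along(f_vals))[seq_len(k)]
    center <- colMeans(xtr[, sel, drop = FALSE])
    scale_sd <- apply(xtr[, sel, drop = FALSE], 2, sd)
    standardise <- function(m, rows) {
      x <- sweep(m[rows, sel, drop = FALSE], 2, center)
      x <- sweep(x, 2, ifelse(scale_sd > 0, scale_sd, 1), "/")
      x[, scale_sd == 0] <- 0
      x
    }
    xw_train <- standardise(mw, train)
    yc <- y[train] - mean(y[train])
    xc <- sweep(xw_train, 2, colMeans(xw_train))
    list(train = train, standardise = standardise, xw_train = xw_train,
         lambda_max = 2 * max(abs(crossprod(xc, yc))))
  })
  lambda_max <- max(vapply(fold_fits, `[[`, 0, "lambda_max"))
  if (lambda_max <= 0) lambda_max <- 1
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))

  sse <- numeric(length(grid))
  paths <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    ff <- fold_fits[[i]]
    test <- !ff$train
    paths[[i]] <- cpp_lasso_path(ff$xw_train, y[ff$train], grid,
                                 tol = .path_tol, maxit = .path_maxit)
    x_test <- ff$standardise(mw, test)
    pred <- x_test %*% paths[[i]]$beta +
      matrix(paths[[i]]$intercept, sum(test), length(grid), byrow = TRUE)
    sse <- sse + colSums((pred - y[test])^2)
  }
  mse <- sse / length(y)
  best <- which(mse == min(mse))[1]
  lambda_star <- grid[best]

  preds <- purrr::map_dfr(seq_along(folds), function(i) {
    ff <- fold_fits[[i]]
    test <- !ff$train
    beta <- paths[[i]]$beta[, best]
    b0 <- paths[[i]]$intercept[best]
    score_rows <- function(m) {
      as.vector(ff$standardise(m, test) %*% beta + b0)
    }
    tibble::tibble(
      participant_id = rep(ids[test], 3),
      variant = rep(c("whole", "odd", "even"), each = sum(test)),
      .pred = c(score_rows(mw), score_rows(mo), score_rows(me)),
      fold = folds[i]
    )
  }) |>
    dplyr::arrange(.data$participant_id, .data$variant)

  list(tuned = list(lambda = lambda_star,
                    cv = tibble::tibble(lambda = grid, mse = mse)),
       preds = preds)
}

#' @export
print.symptom_models <- function(x, ...) {
  cat("Facial symptom-prediction models\n")
  cat(sprintf("  participants: %d  folds: %d  features/dimension: %d%s\n",
              nrow(x$plan), x$settings$n_folds, x$settings$k,
              if (x$settings$strict_cv) "  (strict CV)" else ""))
  nz <- x$coefficients |>
    dplyr::filter(.data$term != "(Intercept)", .data$estimate != 0) |>
    dplyr::count(.data$dimension)
  info <- dplyr::left_join(x$lambda, nz, by = "dimension")
  for (i in seq_len(nrow(info))) {
    cat(sprintf("  %s: lambda = %.4g, %d non-zero coefficients\n",
                .dim_labels[info$dimension[i]], info$lambda[i],
                dplyr::coalesce(info$n[i], 0L)))
  }
  invisible(x)
}

#' Tidy the fitted symptom models
#'
#' @param x A `symptom_models` object.
#' @param ... Unused.
#' @return A tibble of full-data coefficients at the tuned penalty:
#'   `dimension`, `term`, `estimate`.
#' @export
tidy.symptom_models <- function(x, ...) {
  x$coefficients
}

#' One-row-per-dimension summary of the fitted models
#'
#' @param x A `symptom_models` object.
#' @param ... Unused.
#' @return A tibble with `dimension`, `lambda`, `oof_mse`, `n_nonzero`.
#' @export
glance.symptom_models <- function(x, ...) {
  nz <- x$coefficients |>
    dplyr::filter(.data$term != "(Intercept)", .data$estimate != 0) |>
    dplyr::count(.data$dimension, name = "n_nonzero")
  x$lambda |>
    dplyr::left_join(nz, by = "dimension") |>
    dplyr::mutate(n_nonzero = dplyr::coalesce(.data$n_nonzero, 0L))
}
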