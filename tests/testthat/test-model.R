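test_that("the univariate F statistic matches the OLS decomposition", {
  expect_equal(f_statistic(c(1, 2, 3, 4), c(2, 4, 6, 8)), Inf)
  expect_equal(f_statistic(rep(1, 10), rnorm(10)), 0)
  expect_error(f_statistic(rnorm(10), rep(2, 10)), "constant")
  expect_error(f_statistic(1:3, 1:4), "same length")

  set.seed(55)
  for (i in 1:25) {
    feature <- rnorm(100)
    y <- 0.3 * feature + rnorm(100)
    expect_equal(f_statistic(feature, y), oracle_f_ols(feature, y),
                 tolerance = 1e-8)
  }
})

test_that("top-k selection finds planted winners and keeps canonical order", {
  set.seed(9)
  y <- rnorm(40)
  x <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(NULL, sprintf("col%02d", 1:20)))
  x[, c(4, 11, 17)] <- y # forced perfect winners
  features <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%04d", 1:40)),
    tibble::as_tibble(x)
  )
  rule <- select_top_k(features, y, k = 3)
  expect_equal(sort(rule$column), c("col04", "col11", "col17"))
  # ties (all Inf) resolved by canonical column order
  expect_equal(rule$column, c("col04", "col11", "col17"))
  expect_false(is.unsorted(rev(rule$f_value))) # non-increasing, Inf first

  rule50 <- select_top_k(features, y, k = 20)
  expect_equal(nrow(rule50), 20)
  expect_error(select_top_k(features, y, k = 21), "21")
})

test_that("the scaler standardises with whole-data moments only", {
  cohort <- tiny_cohort(n = 6, seed = 2)
  fw <- cohort_features(cohort$recordings, "whole")
  fo <- cohort_features(cohort$recordings, "odd")
  y <- score_subscales(cohort$responses)
  y <- y$raw[y$dimension == "dep"]
  rule <- select_top_k(fw, y, k = 10)
  scaler <- fit_scaler(fw, rule)

  xw <- apply_scaler(fw, scaler)
  expect_equal(unname(colMeans(xw)), rep(0, 10), tolerance = 1e-12)
  nz <- scaler$scale > 0
  expect_equal(unname(apply(xw[, nz], 2, sd)), rep(1, sum(nz)),
               tolerance = 1e-12)

  xo <- apply_scaler(fo, scaler)
  own <- scale(as.matrix(fo[, rule$column]))
  expect_false(isTRUE(all.equal(unname(xo), unname(own))))

  # zero-variance columns map to zero, never NaN
  fz <- fw
  fz[[rule$column[1]]] <- 3
  sc2 <- fit_scaler(fz, rule)
  xz <- apply_scaler(fz, sc2)
  expect_true(all(xz[, 1] == 0))
  expect_true(all(is.finite(xz)))
})

test_that("lasso solutions satisfy closed-form oracles and KKT conditions", {
  set.seed(21)
  n <- 60; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- x %*% c(2, -1, rep(0, p - 2)) + rnorm(n)

  # full shrinkage
  big <- fit_lasso(x, y, lambda = 1e6)
  expect_true(all(big$beta == 0))
  expect_equal(big$intercept, mean(y))

  # lambda = 0 equals OLS from the normal equations
  f0 <- fit_lasso(x, y, lambda = 0)
  xc <- cbind(1, x)
  ols <- solve(crossprod(xc), crossprod(xc, y))
  expect_equal(unname(c(f0$intercept, f0$beta)), unname(as.vector(ols)),
               tolerance = 1e-6)

  # orthonormal-design soft-thresholding (columns centred, unit norm)
  xo <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  yo <- rnorm(n)
  lam <- 0.3
  fo <- fit_lasso(xo, yo, lambda = lam)
  b_ols <- as.vector(crossprod(xo, yo - mean(yo)))
  expect_equal(unname(fo$beta), oracle_soft(b_ols, lam / 2),
               tolerance = 1e-6)

  # KKT subgradient conditions at a generic lambda
  lam2 <- 5
  fit <- fit_lasso(x, y, lambda = lam2)
  r <- y - fit$intercept - x %*% fit$beta
  grad <- -2 * as.vector(crossprod(x, r))
  active <- fit$beta != 0
  expect_true(all(abs(grad[active] + lam2 * sign(fit$beta[active])) < 1e-6))
  expect_true(all(abs(grad[!active]) <= lam2 + 1e-6))

  # objective no worse than the null fit or random perturbations
  obj <- lasso_objective(x, y, fit$beta, fit$intercept, lam2)
  expect_lte(obj, lasso_objective(x, y, rep(0, p), mean(y), lam2))
  set.seed(1)
  for (i in 1:100) {
    pert <- fit$beta + rnorm(p, sd = 0.05)
    expect_lte(obj, lasso_objective(x, y, pert, fit$intercept, lam2) + 1e-9)
  }
})

test_that("lasso agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 80; p <- 12
  x <- scale(matrix(rnorm(n * p), n, p))
  y <- as.vector(x[, 1] - 0.5 * x[, 2] + rnorm(n))
  for (lam in c(2, 10, 40)) {
    ours <- fit_lasso(x, y, lambda = lam)
    # glmnet minimises RSS/(2n) + lambda_g * |beta|; ours RSS + lambda * |beta|
    g <- glmnet::glmnet(x, y, lambda = lam / (2 * n), standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(ours$beta), as.vector(g$beta), tolerance = 1e-4)
  }
})

test_that("fold plans partition participants into near-equal folds", {
  ids <- sprintf("P%04d", 1:103)
  plan <- make_fold_plan(ids, n_folds = 5, seed = 7)
  expect_setequal(plan$participant_id, ids)
  sizes <- table(plan$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(plan, make_fold_plan(ids, n_folds = 5, seed = 7))
  expect_error(make_fold_plan(c("a", "a", "b"), 2, 1), "duplicate")
})

test_that("penalty tuning prefers the null model on noise and fits signal", {
  set.seed(42)
  n <- 100; p <- 15
  ids <- sprintf("P%04d", 1:n)
  plan <- make_fold_plan(ids, seed = 3)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(ids, sprintf("v%02d", 1:p)))

  y_noise <- rnorm(n)
  grid <- lambda_grid(x, y_noise)
  tuned <- tune_lambda(x, y_noise, plan, grid)
  expect_gte(tuned$lambda, sort(grid, decreasing = TRUE)[10])

  # exhaustive-grid oracle: recompute the CV curve independently
  oracle_mse <- vapply(grid, function(l) {
    sse <- 0
    for (f in 1:5) {
      test <- plan$fold == f
      fit <- fit_lasso(x[!test, ], y_noise[!test], l)
      pred <- x[test, ] %*% fit$beta + fit$intercept
      sse <- sse + sum((pred - y_noise[test])^2)
    }
    sse / n
  }, 1)
  expect_equal(tuned$cv$mse, oracle_mse, tolerance = 1e-3)

  y_signal <- as.vector(x %*% c(3, -2, rep(0, p - 2))) + rnorm(n, sd = 0.3)
  tuned_s <- tune_lambda(x, y_signal, plan, lambda_grid(x, y_signal))
  expect_lt(tuned_s$lambda, max(grid))
  expect_equal(tune_lambda(x, y_signal, plan, 7)$lambda, 7)
})

test_that("out-of-fold predictions are aligned, leak-free and recover signal", {
  set.seed(14)
  n <- 80; p <- 10
  ids <- sprintf("P%04d", 1:n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(ids, sprintf("v%02d", 1:p)))
  y <- as.vector(x %*% c(4, -3, 2, rep(0, p - 3)))
  plan <- make_fold_plan(ids, seed = 5)

  preds <- out_of_fold_predict(x, x, x, y, lambda = 0.5, plan = plan)
  expect_equal(nrow(preds), n * 3)
  wide <- tidyr::pivot_wider(preds, id_cols = "participant_id",
                             names_from = "variant", values_from = ".pred")
  expect_equal(wide$whole, wide$odd)
  expect_equal(wide$whole, wide$even)

  whole <- preds[preds$variant == "whole", ]
  expect_gt(cor(whole$.pred, y[match(whole$participant_id, ids)]), 0.9)

  # fold provenance: each prediction comes from the held-out fold's model
  expect_equal(whole$fold,
               plan$fold[match(whole$participant_id, plan$participant_id)])

  # permuting row order leaves each participant's prediction unchanged
  perm <- sample(n)
  preds_p <- out_of_fold_predict(x[perm, ], x[perm, ], x[perm, ], y[perm],
                                 lambda = 0.5, plan = plan)
  whole_p <- preds_p[preds_p$variant == "whole", ]
  expect_equal(
    whole_p$.pred[match(whole$participant_id, whole_p$participant_id)],
    whole$.pred
  )
})

test_that("the fitted model set is deterministic and structurally complete", {
  cohort <- tiny_cohort(n = 10, seed = 6)
  scores <- score_subscales(cohort$responses)
  feats <- facemotion:::.cohort_feature_set(cohort)
  fit_a <- fit_symptom_models(feats$whole, feats$odd, feats$even, scores,
                              k = 20, seed = 2, n_lambda = 30)
  fit_b <- fit_symptom_models(feats$whole, feats$odd, feats$even, scores,
                              k = 20, seed = 2, n_lambda = 30)
  expect_identical(fit_a$predictions, fit_b$predictions)
  expect_identical(fit_a$lambda, fit_b$lambda)

  expect_equal(nrow(fit_a$predictions), 10 * 6 * 3)
  expect_equal(nrow(fit_a$selection), 6 * 20)
  expect_true(all(table(fit_a$selection$dimension) == 20))
  expect_setequal(unique(as.character(fit_a$predictions$variant)),
                  c("whole", "odd", "even"))
  g <- glance(fit_a)
  expect_equal(nrow(g), 6)
  expect_true(all(g$n_nonzero >= 0))
  td <- tidy(fit_a)
  expect_true(all(c("dimension", "term", "estimate") %in% names(td)))

  # strict mode produces the same shape
  fit_s <- fit_symptom_models(feats$whole, feats$odd, feats$even, scores,
                              k = 20, seed = 2, n_lambda = 30,
                              strict_cv = TRUE)
  expect_equal(nrow(fit_s$predictions), 10 * 6 * 3)
})

test_that("whole-sample selection leaks outcome signal into held-out folds", {
  # on a cohort with no facial signal at all, the default protocol
  # (selection and scaling fit before cross-validation) still yields large
  # out-of-fold criterion correlations; the leakage-free strict mode does not
  leaky <- run_study(n = 100, seed = 9001,
                     params = motion_params(effect_size = 0))
  r2_leaky <- mean(tidy(leaky$eval)$r2)
  expect_gt(r2_leaky, 0.3)

  strict <- run_study(n = 100, seed = 9001,
                      params = motion_params(effect_size = 0),
                      strict_cv = TRUE)
  r2_strict <- mean(tidy(strict$eval)$r2)
  expect_lt(r2_strict, r2_leaky - 0.3)
})
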