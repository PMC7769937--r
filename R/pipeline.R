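#' Run the full study pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, applies the inclusion rules, scores the
#' scale, builds the whole/odd/even feature matrices, fits the six
#' prediction models and evaluates their psychometrics. This is the
#' end-to-end path used by the package's calibration and recovery checks.
#'
#' @param n Cohort size (ignored when `cohort` is supplied).
#' @param seed Integer seed driving the cohort draw and the fold plan.
#' @param cohort Optional pre-built `facial_cohort`.
#' @param trait_corr,params,thresholds Passed to [generate_cohort()].
#' @param k,n_folds,strict_cv,n_lambda,lambda_min_ratio Passed to
#'   [fit_symptom_models()].
#' @return A list of class `facial_study`: `cohort`, `screening`, `scores`,
#'   `fit` (`symptom_models`), `eval` (`psychometric_eval`).
#' @examples
#' \donttest{
#' study <- run_study(n = 30, seed = 1)
#' tidy(study$eval)
#' }
#' @export
run_study <- function(n = 100, seed = 1, cohort = NULL,
                      trait_corr = default_trait_corr(),
                      params = motion_params(),
                      thresholds = c(-1.5, -0.5, 0.5, 1.5),
                      k = 50, n_folds = 5, strict_cv = FALSE,
                      n_lambda = 100, lambda_min_ratio = 1e-4) {
  if (is.null(cohort)) {
    cohort <- .generate_cohort(n, seed, trait_corr, params, thresholds,
                               with_tibble = FALSE)
  }
  screening <- screen_participants(cohort$responses, cohort)
  keep <- screening$participant_id[screening$included]
  responses <- cohort$responses |>
    dplyr::filter(.data$participant_id %in% keep)
  scores <- score_subscales(responses)

  mats <- .cohort_matrices(cohort)
  feats <- .cohort_feature_set(mats[names(mats) %in% keep])
  fit <- fit_symptom_models(feats$whole, feats$odd, feats$even, scores,
                            k = k, n_folds = n_folds, seed = seed,
                            strict_cv = strict_cv, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
  structure(
    list(cohort = cohort, screening = screening, scores = scores,
         features = feats, fit = fit,
         eval = evaluate_models(fit, scores)),
    class = "facial_study"
  )
}

#' @export
print.facial_study <- function(x, ...) {
  cat(sprintf("Facial symptom study: %d/%d participants included\n",
              sum(x$screening$included), nrow(x$screening)))
  print(x$eval)
  invisible(x)
}
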