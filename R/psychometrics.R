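#' Pearson correlation with a two-sided p value
#'
#' Standard Pearson r with the p value from the t transform on n - 2
#' degrees of freedom (as computed by [stats::cor.test()]).
#'
#' @param a,b Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 3) abort("correlation needs at least 3 pairs.")
  if (sd(a) == 0 || sd(b) == 0) abort("correlation of a constant vector is undefined.")
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

.significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# predictions tibble -> participants x dimensions matrix for one variant
.pred_wide <- function(predictions, which_variant) {
  predictions |>
    dplyr::filter(.data$variant == which_variant) |>
    dplyr::select("participant_id", "dimension", ".pred") |>
    tidyr::pivot_wider(names_from = "dimension", values_from = ".pred") |>
    dplyr::arrange(.data$participant_id)
}

#' Split-half reliability of the prediction models
#'
#' The Pearson correlation, per dimension, between the predictions computed
#' from the odd-frame and even-frame halves of the same recordings. Reported
#' uncorrected (`r1`); the Spearman-Brown step-up `2r / (1 + r)` is included
#' as a separate, clearly labelled column.
#'
#' @param predictions Prediction tibble from a [fit_symptom_models()] fit
#'   (or the fit object itself).
#' @return A tibble with `dimension`, `r1`, `p`, `stars`, `r1_spearman_brown`.
#' @export
split_half_reliability <- function(predictions) {
  predictions <- .as_predictions(predictions)
  odd <- .pred_wide(predictions, "odd")
  even <- .pred_wide(predictions, "even")
  if (!identical(odd$participant_id, even$participant_id)) {
    abort("odd and even predictions cover different participants.")
  }
  purrr::map_dfr(.dim_codes, function(d) {
    ct <- pearson_r(odd[[d]], even[[d]])
    tibble::tibble(dimension = d, r1 = ct$r, p = ct$p)
  }) |>
    dplyr::mutate(
      dimension = factor(.data$dimension, levels = .dim_codes),
      stars = .significance_stars(.data$p),
      r1_spearman_brown = 2 * .data$r1 / (1 + .data$r1)
    )
}

#' Criterion validity of the prediction models
#'
#' The Pearson correlation, per dimension, between the whole-data
#' out-of-fold predictions and the actual raw subscale scores.
#'
#' @inheritParams split_half_reliability
#' @param scores Long score tibble from [score_subscales()].
#' @return A tibble with `dimension`, `r2`, `p`, `stars`.
#' @export
criterion_validity <- function(predictions, scores) {
  predictions <- .as_predictions(predictions)
  whole <- .pred_wide(predictions, "whole")
  actual <- .scores_wide(scores)
  if (!identical(whole$participant_id, actual$participant_id)) {
    abort("predictions and scores cover different participants.")
  }
  purrr::map_dfr(.dim_codes, function(d) {
    ct <- pearson_r(whole[[d]], actual[[d]])
    tibble::tibble(dimension = d, r2 = ct$r, p = ct$p)
  }) |>
    dplyr::mutate(
      dimension = factor(.data$dimension, levels = .dim_codes),
      stars = .significance_stars(.data$p)
    )
}

.scores_wide <- function(scores) {
  scores |>
    dplyr::select("participant_id", "dimension", "raw") |>
    tidyr::pivot_wider(names_from = "dimension", values_from = "raw") |>
    dplyr::arrange(.data$participant_id)
}

.as_predictions <- function(x) {
  if (inherits(x, "symptom_models")) x$predictions else x
}
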