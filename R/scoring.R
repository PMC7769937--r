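#' Score SCL-90 item responses into the six subscales
#'
#' Raw subscale scores are item sums; factor scores are raw scores divided by
#' the subscale's item count, so they live on the 1--5 response scale.
#'
#' @param responses A tibble with `participant_id` and integer columns
#'   `item_01` ... `item_55`, each in 1--5.
#' @return A long tibble with one row per participant and dimension:
#'   `participant_id`, `dimension`, `n_items`, `raw`, `factor_score`.
#' @examples
#' traits <- generate_traits(4, seed = 1)
#' score_subscales(generate_scl90_responses(traits, seed = 2))
#' @export
score_subscales <- function(responses) {
  .check_responses(responses)
  dims <- scl90_dimensions()
  long <- responses |>
    tidyr::pivot_longer(dplyr::all_of(.item_cols()),
                        names_to = "item", values_to = "response") |>
    dplyr::left_join(scl90_item_map(), by = "item")
  long |>
    dplyr::group_by(.data$participant_id, .data$dimension) |>
    dplyr::summarise(raw = sum(.data$response), .groups = "drop") |>
    dplyr::left_join(dims[, c("dimension", "n_items")], by = "dimension") |>
    dplyr::mutate(
      factor_score = .data$raw / .data$n_items,
      dimension = factor(.data$dimension, levels = .dim_codes)
    ) |>
    dplyr::arrange(.data$participant_id, .data$dimension) |>
    dplyr::select("participant_id", "dimension", "n_items", "raw",
                  "factor_score")
}

.check_responses <- function(responses) {
  missing <- setdiff(c("participant_id", .item_cols()), names(responses))
  if (length(missing) > 0) {
    abort(sprintf("`responses` is missing column(s): %s.",
                  paste(head(missing, 3), collapse = ", ")))
  }
  for (col in .item_cols()) {
    v <- responses[[col]]
    bad <- is.na(v) | v %% 1 != 0 | v < 1 | v > 5
    if (any(bad)) {
      abort(sprintf(
        "invalid response in %s for participant %s (value %s); responses must be integers in 1-5.",
        col, responses$participant_id[which(bad)[1]],
        as.character(v[which(bad)[1]])
      ))
    }
  }
  invisible(responses)
}

#' Classify participants on the six-subscale total score
#'
#' Participants at or above the [scl90_threshold()] of 110 points (the
#' factor-score-2 rule summed over the 55 measured items) are labelled
#' `mentally_ill`, others `healthy`.
#'
#' @param scores Long score tibble from [score_subscales()].
#' @return A tibble with `participant_id`, `total` and `group`.
#' @export
classify_group <- function(scores) {
  threshold <- scl90_threshold()
  scores |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(total = sum(.data$raw), .groups = "drop") |>
    dplyr::mutate(group = factor(
      ifelse(.data$total >= threshold, "mentally_ill", "healthy"),
      levels = c("healthy", "mentally_ill")
    ))
}

#' Apply the cohort inclusion rules
#'
#' A participant is excluded when all 55 responses are the scale minimum,
#' when all are the scale maximum, or when the recording is shorter than
#' `min_frames` (700) frames; a recording of exactly 700 frames is included.
#'
#' @param responses Item-response tibble.
#' @param recordings Long landmark tibble covering the same participants (a
#'   `facial_cohort` is also accepted).
#' @param min_frames Minimum frame count for inclusion.
#' @return A tibble with `participant_id`, `n_frames`, `included` and
#'   `reason` (`NA` for included participants, otherwise `"all_minimum"`,
#'   `"all_maximum"` or `"too_few_frames"`).
#' @export
screen_participants <- function(responses, recordings, min_frames = 700) {
  .check_responses(responses)
  resp_mat <- as.matrix(responses[, .item_cols()])
  all_min <- rowSums(resp_mat == 1L) == 55L
  all_max <- rowSums(resp_mat == 5L) == 55L
  if (!is.data.frame(recordings)) {
    mats <- .cohort_matrices(recordings)
    frame_counts <- tibble::tibble(
      participant_id = names(mats),
      n_frames = vapply(mats, nrow, 1L)
    )
  } else {
    frame_counts <- recordings |>
      dplyr::distinct(.data$participant_id, .data$frame) |>
      dplyr::count(.data$participant_id, name = "n_frames")
  }
  tibble::tibble(
    participant_id = responses$participant_id,
    all_min = all_min,
    all_max = all_max
  ) |>
    dplyr::left_join(frame_counts, by = "participant_id") |>
    dplyr::mutate(
      n_frames = dplyr::coalesce(.data$n_frames, 0L),
      reason = dplyr::case_when(
        all_min ~ "all_minimum",
        all_max ~ "all_maximum",
        .data$n_frames < min_frames ~ "too_few_frames",
        TRUE ~ NA_character_
      ),
      included = is.na(.data$reason)
    ) |>
    dplyr::select("participant_id", "n_frames", "included", "reason")
}
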