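#' Translate coordinates to the reference key point
#'
#' Subtracts key point 0's coordinates from every point, frame by frame, so
#' that rigid head translations (shared by all points) cancel exactly and
#' point 0 becomes the origin in every frame.
#'
#' @param rec A long landmark tibble (`participant_id`, `frame`, `point_id`,
#'   `x`, `y`, `z`); one or more participants.
#' @return A tibble of the same shape.
#' @export
translate_to_reference <- function(rec) {
  ref <- rec |>
    dplyr::filter(.data$point_id == 0L) |>
    dplyr::select("participant_id", "frame",
                  ref_x = "x", ref_y = "y", ref_z = "z")
  rec |>
    dplyr::left_join(ref, by = c("participant_id", "frame")) |>
    dplyr::mutate(
      x = .data$x - .data$ref_x,
      y = .data$y - .data$ref_y,
      z = .data$z - .data$ref_z
    ) |>
    dplyr::select(-"ref_x", -"ref_y", -"ref_z")
}

#' Three-frame moving-average smoothing
#'
#' Replaces each interior frame's coordinates with the mean of the previous,
#' current and next frame (computed from the original recording, not in
#' place); the first and last frames pass through unchanged, so the frame
#' count is preserved. Linear trajectories are unchanged on interior frames.
#'
#' @inheritParams translate_to_reference
#' @return A tibble of the same shape.
#' @export
smooth_three_frame <- function(rec) {
  rec |>
    dplyr::group_by(.data$participant_id, .data$point_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(c("x", "y", "z"), .smooth3)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$frame, .data$point_id)
}

.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) abort(sprintf("smoothing needs at least 3 frames; got %d.", n))
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

#' Keep the analysis window of frames
#'
#' Retains the frames at 0-based positions `[start, start + length)` within
#' each participant's recording (by frame order, not frame label), dropping
#' the preparation time before and after the task. With the defaults this is
#' the 100th to 700th frame, i.e. exactly 600 retained frames.
#'
#' @inheritParams translate_to_reference
#' @param start First retained 0-based frame position.
#' @param length Number of retained frames.
#' @return A tibble with `length` frames per participant.
#' @export
window_frames <- function(rec, start = 100, length = 600) {
  rec |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      frames <- sort(unique(df$frame))
      n_avail <- base::length(frames)
      if (n_avail < start + length) {
        abort(sprintf(
          "recording for %s has %d frames; windowing [%d, %d) needs at least %d.",
          key$participant_id, n_avail, start, start + length,
          start + length
        ))
      }
      keep <- frames[(start + 1):(start + length)]
      df[df$frame %in% keep, , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$frame, .data$point_id)
}

#' Split a windowed recording into parity halves
#'
#' Partitions the frames of each participant by the parity of their 0-based
#' position: even positions form the `even` half, odd positions the `odd`
#' half. A 600-frame window yields two 300-frame halves; interleaving the
#' halves reconstructs the window.
#'
#' @inheritParams translate_to_reference
#' @return A named list with tibbles `odd` and `even`.
#' @export
split_half <- function(rec) {
  counts <- rec |>
    dplyr::distinct(.data$participant_id, .data$frame) |>
    dplyr::count(.data$participant_id)
  if (any(counts$n %% 2 != 0)) {
    bad <- counts$participant_id[counts$n %% 2 != 0][1]
    abort(sprintf(
      "split_half needs an even frame count; %s has %d frames.",
      bad, counts$n[counts$participant_id == bad]
    ))
  }
  with_pos <- rec |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.pos = match(.data$frame, sort(unique(.data$frame))) - 1L) |>
    dplyr::ungroup()
  out <- list(
    odd = with_pos |> dplyr::filter(.data$.pos %% 2L == 1L),
    even = with_pos |> dplyr::filter(.data$.pos %% 2L == 0L)
  )
  lapply(out, function(df) dplyr::select(df, -".pos"))
}

#' First-difference the coordinate series
#'
#' Computes the per-frame coordinate changes `x[t+1] - x[t]` for every point
#' and axis, the motion quantity that all downstream features are computed
#' on. A recording of `F` frames yields 36 x 3 = 108 change series of length
#' `F - 1`.
#'
#' @inheritParams translate_to_reference
#' @return A long motion tibble: `participant_id`, `point_id`, `axis`,
#'   `step` (1-based change index), `delta`.
#' @export
difference_series <- function(rec) {
  counts <- rec |>
    dplyr::distinct(.data$participant_id, .data$frame) |>
    dplyr::count(.data$participant_id)
  if (any(counts$n < 2)) {
    abort("differencing needs at least 2 frames per participant.")
  }
  rec |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis",
                        values_to = "value") |>
    dplyr::group_by(.data$participant_id, .data$point_id, .data$axis) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(step = seq_len(dplyr::n() - 1L),
                   delta = diff(.data$value)) |>
    dplyr::arrange(.data$participant_id, .data$point_id, .data$axis,
                   .data$step)
}

#' Full preprocessing pipeline for one variant
#'
#' Composes the four preprocessing steps in order -- reference-point
#' translation, three-frame smoothing, frame windowing, and differencing --
#' optionally keeping only the odd- or even-position half of the windowed
#' frames before differencing. A 720-frame recording gives change series of
#' length 599 (`whole`) or 299 (`odd`/`even`).
#'
#' @inheritParams translate_to_reference
#' @param variant `"whole"`, `"odd"` or `"even"`.
#' @param start,length Analysis window, as in [window_frames()].
#' @return A long motion tibble with a `variant` column.
#' @export
preprocess_recording <- function(rec, variant = c("whole", "odd", "even"),
                                 start = 100, length = 600) {
  variant <- match.arg(variant)
  windowed <- rec |>
    translate_to_reference() |>
    smooth_three_frame() |>
    window_frames(start = start, length = length)
  if (variant != "whole") {
    windowed <- split_half(windowed)[[variant]]
  }
  difference_series(windowed) |>
    dplyr::mutate(variant = variant, .after = "participant_id")
}

# matrix-path core used by cohort_features(); must agree with the tibble ops
# (asserted in the test suite)
.window_matrix <- function(m, start = 100, length = 600) {
  n_frames <- nrow(m)
  if (n_frames < start + length) {
    abort(sprintf("recording has %d frames; need at least %d.",
                  n_frames, start + length))
  }
  m <- m - m[, rep(1:3, times = 36L)]
  s <- m
  s[2:(n_frames - 1), ] <-
    (m[1:(n_frames - 2), ] + m[2:(n_frames - 1), ] + m[3:n_frames, ]) / 3
  s[(start + 1):(start + length), , drop = FALSE]
}

.variant_diff <- function(w, variant = "whole") {
  len <- nrow(w)
  if (variant == "even") {
    w <- w[seq(1, len, by = 2), , drop = FALSE]
  } else if (variant == "odd") {
    w <- w[seq(2, len, by = 2), , drop = FALSE]
  }
  w[-1L, , drop = FALSE] - w[-nrow(w), , drop = FALSE]
}

.preprocess_matrix <- function(m, variant = "whole", start = 100,
                               length = 600) {
  .variant_diff(.window_matrix(m, start, length), variant)
}
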