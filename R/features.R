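#' Names of the 30 time-series characteristics
#'
#' The catalogue of scalar summaries applied to every coordinate-change
#' series, in the fixed order used throughout the feature matrix. Boolean
#' characteristics are encoded as 0/1 so the matrix is uniformly numeric.
#'
#' Estimator conventions: `variance` uses the population denominator `n`
#' (and `std` its square root); `skewness` is the adjusted Fisher-Pearson
#' sample skewness and `kurtosis` the adjusted sample excess kurtosis, both
#' defined as 0 for constant series or when too few observations exist
#' (n < 3, resp. n < 4); `first_loc_*` are 0-based-index/n and `last_loc_*`
#' 1-based-index/n; counts and strikes around the mean are strict;
#' `sum_reoccurring_points` sums duplicated values with multiplicity while
#' `sum_reoccurring_values` counts each duplicated value once;
#' `ratio_unique_values` is the number of distinct values over n.
#'
#' @return A character vector of length 30.
#' @export
ts_characteristic_names <- function() {
  c("maximum", "minimum", "mean", "variance", "std", "skewness", "kurtosis",
    "median", "abs_energy", "abs_sum_changes", "var_gt_std",
    "count_above_mean", "count_below_mean", "first_loc_max", "last_loc_max",
    "first_loc_min", "last_loc_min", "has_duplicate", "has_duplicate_max",
    "has_duplicate_min", "longest_strike_above_mean",
    "longest_strike_below_mean", "mean_abs_change", "mean_change",
    "pct_reoccurring_points", "ratio_unique_values",
    "sum_reoccurring_points", "sum_reoccurring_values", "sum_values",
    "range")
}

#' Compute the 30 characteristics of one series
#'
#' @param x A numeric series of finite values, length at least 2.
#' @return A named numeric vector of length 30 (see
#'   [ts_characteristic_names()] for the definitions).
#' @examples
#' compute_characteristics(c(1, 2, 2, 3))
#' @export
compute_characteristics <- function(x) {
  if (length(x) < 2) {
    abort(sprintf("series must have at least 2 values; got %d.", length(x)))
  }
  if (!all(is.finite(x))) abort("series contains non-finite values.")
  out <- cpp_characteristics(matrix(as.double(x), ncol = 1))[, 1]
  setNames(out, ts_characteristic_names())
}

#' Canonical feature-matrix column names
#'
#' Column order is point-major, axis-middle, characteristic-minor:
#' `point00_x_maximum`, ..., `point00_x_range`, `point00_y_maximum`, ...,
#' `point35_z_range`; 36 x 3 x 30 = 3,240 columns in total.
#'
#' @return A character vector of length 3,240.
#' @export
feature_columns <- function() {
  paste0(rep(.coord_cols(), each = 30), "_",
         rep(ts_characteristic_names(), times = 108))
}

# motion tibble (one participant, one variant) -> steps x 108 matrix
.motion_to_matrix <- function(motion) {
  key <- paste0(sprintf("point%02d", motion$point_id), "_", motion$axis)
  expected <- .coord_cols()
  missing <- setdiff(expected, unique(key))
  if (length(missing) > 0) {
    abort(sprintf("motion series missing for %s.", missing[1]))
  }
  steps <- sort(unique(motion$step))
  m <- matrix(NA_real_, length(steps), 108L,
              dimnames = list(NULL, expected))
  m[cbind(match(motion$step, steps), match(key, expected))] <- motion$delta
  if (anyNA(m)) abort("motion series have unequal or incomplete steps.")
  m
}

# 30 x 108 characteristic block -> named 3,240-vector (canonical order)
.flatten_characteristics <- function(block) {
  setNames(as.vector(block), feature_columns())
}

#' Extract the 3,240-column feature row for one participant
#'
#' Applies the 30-characteristic catalogue to each of the 108 per-point,
#' per-axis coordinate-change series of one preprocessed recording.
#'
#' @param motion A motion tibble from [preprocess_recording()] (one
#'   participant, one variant).
#' @return A one-row tibble: `participant_id` plus 3,240 named feature
#'   columns.
#' @export
extract_features <- function(motion) {
  ids <- unique(motion$participant_id)
  if (length(ids) != 1) {
    abort("`motion` must contain exactly one participant; use build_feature_matrix() for cohorts.")
  }
  m <- .motion_to_matrix(motion)
  vals <- .flatten_characteristics(cpp_characteristics(m))
  dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    tibble::as_tibble(as.list(vals))
  )
}

#' Build the participants x 3,240 feature matrix
#'
#' @param motion A motion tibble covering one variant of every participant.
#' @return A tibble with `participant_id` and the 3,240 canonical feature
#'   columns, one row per participant (zero rows for an empty cohort).
#' @export
build_feature_matrix <- function(motion) {
  ids <- unique(motion$participant_id)
  if (anyDuplicated(ids)) abort("duplicate participant ids in motion data.")
  if (length(ids) == 0) {
    empty <- tibble::as_tibble(setNames(
      c(list(character()), rep(list(double()), 3240)),
      c("participant_id", feature_columns())
    ))
    return(empty)
  }
  motion |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(extract_features)
}

#' Fast cohort path from raw recordings to a feature matrix
#'
#' Equivalent to preprocessing every recording with
#' [preprocess_recording()] and stacking [extract_features()] rows, but runs
#' on per-participant coordinate matrices for speed. The equivalence of the
#' two routes is asserted in the package's test suite.
#'
#' @param recordings A long landmark tibble over one or more participants,
#'   or a `facial_cohort` (whose cached coordinate matrices are then used
#'   directly).
#' @param variant `"whole"`, `"odd"` or `"even"`.
#' @param start,length Analysis window, as in [window_frames()].
#' @return A feature tibble as from [build_feature_matrix()].
#' @export
cohort_features <- function(recordings, variant = c("whole", "odd", "even"),
                            start = 100, length = 600) {
  variant <- match.arg(variant)
  mats <- .cohort_matrices(recordings)
  if (length(mats) == 0) {
    return(build_feature_matrix(tibble::tibble(participant_id = character(),
                                               point_id = integer(),
                                               axis = character(),
                                               step = integer(),
                                               delta = double())))
  }
  rows <- lapply(mats, function(m) {
    d <- .preprocess_matrix(m, variant, start = start, length = length)
    .flatten_characteristics(cpp_characteristics(d))
  })
  .assemble_features(names(mats), rows)
}

# all three variants in one preprocessing pass per participant
.cohort_feature_set <- function(recordings, start = 100, length = 600) {
  mats <- .cohort_matrices(recordings)
  per_variant <- list(whole = list(), odd = list(), even = list())
  for (id in names(mats)) {
    w <- .window_matrix(mats[[id]], start = start, length = length)
    for (v in names(per_variant)) {
      per_variant[[v]][[id]] <-
        .flatten_characteristics(cpp_characteristics(.variant_diff(w, v)))
    }
  }
  lapply(per_variant, function(rows) .assemble_features(names(mats), rows))
}

.assemble_features <- function(ids, rows) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    tibble::as_tibble(mat)
  )
}

# per-participant frames x 108 matrices from a cohort, a named list of
# matrices, or a long tibble
.cohort_matrices <- function(recordings) {
  if (inherits(recordings, "facial_cohort")) {
    if (!is.null(recordings$recording_matrices)) {
      return(recordings$recording_matrices)
    }
    recordings <- recordings$recordings
  }
  if (is.list(recordings) && !is.data.frame(recordings)) {
    return(recordings)
  }
  ids <- unique(recordings$participant_id)
  idx <- split(seq_len(nrow(recordings)),
               factor(recordings$participant_id, levels = ids))
  mats <- lapply(idx, function(i) {
    .recording_to_matrix(recordings[i, , drop = FALSE])
  })
  names(mats) <- ids
  mats
}
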