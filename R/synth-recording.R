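#' Motion-model parameters for the synthetic recording generator
#'
#' The generator writes, per frame, `anchor + head translation + wobble +
#' jitter` for every key point. The wobble is a stationary AR(1) process per
#' point/axis whose stationary standard deviation is the point's motion
#' amplitude; the head translation is a 3D random walk shared by all 36
#' points (so it is exactly removed by reference-point translation); the
#' jitter is independent per-frame measurement noise.
#'
#' A point's amplitude is
#' `baseline_amplitude * max(0, 1 + effect_size[d] * trait[d] * side_weight)`,
#' where `d` is the dimension assigned to that point in the key-point schema
#' (midline points have no assigned dimension and stay at baseline), and the
#' side weight is `2 * laterality` for left-face points, `2 * (1 -
#' laterality)` for right-face points and 1 for midline points. With
#' `laterality = 0.5` the two sides carry the effect equally; the default 0.8
#' concentrates it on the left side of the face.
#'
#' @param baseline_amplitude Stationary wobble SD at trait 0, in metres
#'   (default 2 mm).
#' @param effect_size Per-dimension linear coefficient mapping a trait to a
#'   relative amplitude change; scalar values are recycled to length 6.
#' @param laterality Fraction of the trait effect carried by the left side of
#'   the face, in `[0, 1]`.
#' @param head_motion_sd Per-frame step SD of the rigid head-translation
#'   random walk, in metres.
#' @param noise_sd Per-frame, per-coordinate jitter SD, in metres.
#' @param n_frames Frames per recording; must be at least 700 (the pipeline's
#'   inclusion bound). Default 720 frames = 24 s at 30 Hz.
#' @param frame_rate Capture rate in Hz.
#' @param ar_coef AR(1) coefficient of the wobble process.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(baseline_amplitude = 0.002,
                          effect_size = 0.15,
                          laterality = 0.8,
                          head_motion_sd = 0.001,
                          noise_sd = 5e-4,
                          n_frames = 720,
                          frame_rate = 30,
                          ar_coef = 0.8) {
  if (length(effect_size) == 1) effect_size <- rep(effect_size, 6)
  if (length(effect_size) != 6) {
    abort("`effect_size` must be a scalar or a length-6 vector.")
  }
  effect_size <- setNames(as.double(effect_size), .dim_codes)
  if (n_frames < 700) {
    abort(sprintf(
      "`n_frames` is %d; recordings under 700 frames violate the inclusion criterion.",
      n_frames
    ))
  }
  scales <- c(baseline_amplitude = baseline_amplitude,
              head_motion_sd = head_motion_sd, noise_sd = noise_sd)
  if (any(scales < 0)) {
    abort(sprintf("`%s` must be non-negative.", names(scales)[scales < 0][1]))
  }
  if (laterality < 0 || laterality > 1) {
    abort("`laterality` must lie in [0, 1].")
  }
  if (abs(ar_coef) >= 1) abort("`ar_coef` must lie in (-1, 1).")
  structure(
    list(baseline_amplitude = baseline_amplitude,
         effect_size = effect_size,
         laterality = laterality,
         head_motion_sd = head_motion_sd,
         noise_sd = noise_sd,
         n_frames = as.integer(n_frames),
         frame_rate = frame_rate,
         ar_coef = ar_coef),
    class = "motion_params"
  )
}

# per-point stationary wobble amplitude for one participant's traits
.point_amplitudes <- function(trait_row, params, schema = key_point_schema()) {
  side_weight <- dplyr::case_when(
    schema$side == "left" ~ 2 * params$laterality,
    schema$side == "right" ~ 2 * (1 - params$laterality),
    TRUE ~ 1
  )
  effect <- ifelse(
    is.na(schema$dimension), 0,
    params$effect_size[schema$dimension] *
      as.numeric(trait_row[schema$dimension])
  )
  params$baseline_amplitude * pmax(0, 1 + effect * side_weight)
}

# core simulator: frames x 108 matrix, canonical column order
# (point 0 x,y,z, point 1 x,y,z, ...). RNG draw order is wobble, jitter,
# head motion, so head_motion_sd does not perturb the other two streams.
.simulate_recording_matrix <- function(trait_row, params, seed) {
  n_frames <- params$n_frames
  schema <- key_point_schema()
  amp <- .point_amplitudes(trait_row, params, schema)
  amp3 <- rep(amp, each = 3L)
  phi <- params$ar_coef

  set.seed(seed)
  innov <- matrix(rnorm(n_frames * 108L), n_frames, 108L)
  innov[1L, ] <- innov[1L, ] * amp3
  if (n_frames > 1) {
    innov[-1L, ] <- innov[-1L, ] *
      rep(sqrt(1 - phi^2) * amp3, each = n_frames - 1L)
  }
  wobble <- cpp_ar1_filter(innov, phi)
  jitter <- matrix(rnorm(n_frames * 108L, sd = params$noise_sd),
                   n_frames, 108L)
  head_walk <- apply(
    matrix(rnorm(n_frames * 3L, sd = params$head_motion_sd), n_frames, 3L),
    2L, cumsum
  )
  head_walk <- matrix(head_walk, n_frames, 3L)

  anchors <- rbind(schema$anchor_x, schema$anchor_y, schema$anchor_z)
  m <- wobble + jitter + head_walk[, rep(1:3, times = 36L)] +
    matrix(as.vector(anchors), n_frames, 108L, byrow = TRUE)
  colnames(m) <- .coord_cols()
  m
}

.coord_cols <- function() {
  paste0(rep(sprintf("point%02d", 0:35), each = 3), "_", rep(.axes, 36))
}

# long tibble <-> frames x 108 matrix
.matrix_to_recording <- function(m, participant_id) {
  n_frames <- nrow(m)
  tibble::tibble(
    participant_id = participant_id,
    frame = rep(seq_len(n_frames) - 1L, each = 36L),
    point_id = rep(0:35, times = n_frames),
    x = as.vector(t(m[, seq(1, 108, by = 3), drop = FALSE])),
    y = as.vector(t(m[, seq(2, 108, by = 3), drop = FALSE])),
    z = as.vector(t(m[, seq(3, 108, by = 3), drop = FALSE]))
  )
}

# stack per-participant matrices into one long tibble in a single pass
.matrices_to_recording <- function(matrices, n_frames) {
  n <- length(matrices)
  if (n == 0) return(.matrix_to_recording(matrix(0, 0, 108), character()))
  big <- do.call(rbind, matrices) # (n * n_frames) x 108
  tibble::tibble(
    participant_id = rep(names(matrices), each = n_frames * 36L),
    frame = rep(rep(seq_len(n_frames) - 1L, each = 36L), times = n),
    point_id = rep(0:35, times = nrow(big)),
    x = as.vector(t(big[, seq(1, 108, by = 3), drop = FALSE])),
    y = as.vector(t(big[, seq(2, 108, by = 3), drop = FALSE])),
    z = as.vector(t(big[, seq(3, 108, by = 3), drop = FALSE]))
  )
}

.recording_to_matrix <- function(rec) {
  .check_recording(rec)
  frames <- sort(unique(rec$frame))
  n_frames <- length(frames)
  m <- matrix(NA_real_, n_frames, 108L, dimnames = list(NULL, .coord_cols()))
  row_idx <- match(rec$frame, frames)
  for (a in 1:3) {
    m[cbind(row_idx, 3L * rec$point_id + a)] <-
      rec[[c("x", "y", "z")[a]]]
  }
  if (anyNA(m)) abort("recording has missing point/frame combinations.")
  m
}

.check_recording <- function(rec) {
  needed <- c("participant_id", "frame", "point_id", "x", "y", "z")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0) {
    abort(sprintf("recording is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (length(unique(rec$participant_id)) > 1) {
    abort("expected a single participant's recording.")
  }
  invisible(rec)
}

#' Generate one synthetic landmark recording
#'
#' Simulates a Kinect-style 30 Hz recording of the 36 facial key points for
#' one participant, as the sum of fixed anchor positions, a rigid
#' head-translation random walk shared by all points, a per-point stationary
#' AR(1) wobble whose amplitude increases linearly with the participant's
#' latent symptom traits (lateralised per [motion_params()]), and independent
#' per-frame jitter.
#'
#' @param trait_row A named length-6 vector (or one-row tibble) of latent
#'   traits, names `int, dep, anx, hos, pho, psy`.
#' @param params A [motion_params()] object.
#' @param seed Integer seed.
#' @param participant_id Id stored in the output.
#' @return A long tibble with columns `participant_id`, `frame` (0-based),
#'   `point_id` (0--35), `x`, `y`, `z`.
#' @examples
#' rec <- generate_recording(c(int = 1, dep = 0, anx = 0, hos = 0, pho = 0, psy = 0),
#'                           motion_params(n_frames = 700), seed = 1)
#' @export
generate_recording <- function(trait_row, params = motion_params(), seed = 1,
                               participant_id = "P0001") {
  if (is.data.frame(trait_row)) trait_row <- unlist(trait_row[1, .dim_codes])
  if (!all(.dim_codes %in% names(trait_row))) {
    abort("`trait_row` must be named with the six dimension codes.")
  }
  m <- .simulate_recording_matrix(trait_row, params, seed)
  .matrix_to_recording(m, participant_id)
}

#' Generate a full synthetic cohort
#'
#' Draws correlated latent traits, SCL-90 item responses and one landmark
#' recording per participant, all reproducible from a single seed. When `dir`
#' is given, writes `landmarks.csv` (long format), `responses.csv`, the
#' item-map sidecar `scl90_items.json` and a `ground_truth.json` bundle
#' (traits, parameters, seed) into it.
#'
#' @param n Number of participants.
#' @param seed Integer seed controlling every random draw.
#' @param trait_corr 6 x 6 latent-trait correlation matrix.
#' @param params A [motion_params()] object.
#' @param thresholds Likert cut points passed to [generate_scl90_responses()].
#' @param dir Optional output directory.
#' @return A list of class `facial_cohort` with elements `recordings` (long
#'   tibble over all participants), `recording_matrices` (the same
#'   coordinates as per-participant frames x 108 matrices, the fast-path
#'   input of [cohort_features()]), `responses`, `traits` and
#'   `ground_truth`.
#' @examples
#' cohort <- generate_cohort(3, seed = 1, params = motion_params(n_frames = 700))
#' @export
generate_cohort <- function(n, seed = 1,
                            trait_corr = default_trait_corr(),
                            params = motion_params(),
                            thresholds = c(-1.5, -0.5, 0.5, 1.5),
                            dir = NULL) {
  cohort <- .generate_cohort(n, seed, trait_corr, params, thresholds,
                             with_tibble = TRUE)
  if (!is.null(dir)) .write_cohort(cohort, dir)
  cohort
}

# with_tibble = FALSE skips the long-tibble assembly (pure simulation
# studies touch only the matrices); the random draws are identical
.generate_cohort <- function(n, seed, trait_corr, params, thresholds,
                             with_tibble = TRUE) {
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, n + 2L)
  traits <- generate_traits(n, trait_corr, seed = sub_seeds[1])
  responses <- generate_scl90_responses(traits, thresholds, seed = sub_seeds[2])
  matrices <- lapply(seq_len(n), function(i) {
    .simulate_recording_matrix(
      unlist(traits[i, .dim_codes]), params, sub_seeds[i + 2L]
    )
  })
  names(matrices) <- traits$participant_id
  structure(
    list(
      recordings = if (with_tibble) {
        .matrices_to_recording(matrices, params$n_frames)
      },
      recording_matrices = matrices,
      responses = responses,
      traits = traits,
      ground_truth = list(
        seed = seed,
        trait_corr = trait_corr,
        params = unclass(params),
        thresholds = thresholds
      )
    ),
    class = "facial_cohort"
  )
}

.write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      abort(sprintf("could not create output directory '%s'.", dir))
    }
  }
  readr::write_csv(cohort$recordings, file.path(dir, "landmarks.csv"))
  readr::write_csv(cohort$responses, file.path(dir, "responses.csv"))
  file.copy(
    system.file("extdata", "scl90_items.json", package = "facemotion"),
    file.path(dir, "scl90_items.json"),
    overwrite = TRUE
  )
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(
      seed = gt$seed,
      trait_corr = gt$trait_corr,
      params = gt$params,
      thresholds = gt$thresholds,
      traits = cohort$traits
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
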