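# Shared small fixtures, built in code.

# a tiny but pipeline-complete cohort (700-frame recordings keep the
# windowing arithmetic intact while halving simulation cost)
tiny_cohort <- function(n = 6, seed = 11, ...) {
  generate_cohort(n, seed = seed,
                  params = motion_params(n_frames = 700, ...))
}

# deterministic single-participant recording from explicit coordinates:
# coords is a frames x 36 x 3 array or a function(frame, point) -> c(x,y,z)
manual_recording <- function(frames, participant_id = "P0001",
                             coords = NULL) {
  grid <- expand.grid(point_id = 0:35, frame = seq_len(frames) - 1L)
  if (is.null(coords)) {
    coords <- function(f, p) c(p + f * 0.1, p - f * 0.1, f * 0.01)
  }
  xyz <- t(mapply(coords, grid$frame, grid$point_id))
  tibble::tibble(
    participant_id = participant_id,
    frame = grid$frame,
    point_id = grid$point_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# item responses with a fixed value everywhere
flat_responses <- function(value, n = 1) {
  stopifnot(value %in% 1:5)
  items <- matrix(as.integer(value), n, 55,
                  dimnames = list(NULL, sprintf("item_%02d", 1:55)))
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%04d", seq_len(n))),
    tibble::as_tibble(items)
  )
}

trait_row_all <- function(value) {
  stats::setNames(rep(value, 6), c("int", "dep", "anx", "hos", "pho", "psy"))
}
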