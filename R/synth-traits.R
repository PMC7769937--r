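#' Default inter-trait correlation matrix
#'
#' Community samples show substantial correlations (roughly 0.3--0.8) among
#' SCL-90 subscales; the default latent-trait correlation matrix places every
#' pair in that band, with the strongest coupling among interpersonal
#' sensitivity, depression, anxiety and psychoticism.
#'
#' @return A 6 x 6 correlation matrix with dimension codes as dimnames.
#' @export
default_trait_corr <- function() {
  r <- matrix(c(
    1.00, 0.65, 0.55, 0.45, 0.40, 0.60,
    0.65, 1.00, 0.70, 0.50, 0.45, 0.60,
    0.55, 0.70, 1.00, 0.45, 0.55, 0.60,
    0.45, 0.50, 0.45, 1.00, 0.30, 0.40,
    0.40, 0.45, 0.55, 0.30, 1.00, 0.45,
    0.60, 0.60, 0.60, 0.40, 0.45, 1.00
  ), 6, 6, dimnames = list(.dim_codes, .dim_codes))
  r
}

#' Generate latent symptom-severity traits
#'
#' Draws one standard-normal latent severity value per participant for each of
#' the six symptom dimensions from a multivariate normal with the given
#' correlation matrix. These traits are the ground truth that both the item
#' responses and the facial motion amplitudes are generated from.
#'
#' @param n Number of participants.
#' @param trait_corr 6 x 6 correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return A tibble with `participant_id` and one column per dimension code.
#' @examples
#' generate_traits(5, seed = 1)
#' @export
generate_traits <- function(n, trait_corr = default_trait_corr(), seed = 1) {
  .check_trait_corr(trait_corr)
  if (n == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character()), rep(list(double()), 6)),
      c("participant_id", .dim_codes)
    ))
    return(out)
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = trait_corr)
  draws <- matrix(draws, nrow = n, ncol = 6)
  colnames(draws) <- .dim_codes
  dplyr::bind_cols(
    tibble::tibble(participant_id = .participant_ids(n)),
    tibble::as_tibble(draws)
  )
}

.participant_ids <- function(n) sprintf("P%04d", seq_len(n))

.check_trait_corr <- function(trait_corr) {
  if (!is.matrix(trait_corr) || !all(dim(trait_corr) == c(6, 6))) {
    abort("`trait_corr` must be a 6 x 6 matrix.")
  }
  if (max(abs(trait_corr - t(trait_corr))) > 1e-8) {
    abort("`trait_corr` must be symmetric.")
  }
  if (max(abs(diag(trait_corr) - 1)) > 1e-8) {
    abort("`trait_corr` must have a unit diagonal.")
  }
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "`trait_corr` is not positive semi-definite (smallest eigenvalue %.6g).",
      min(ev)
    ))
  }
  invisible(trait_corr)
}

#' Generate SCL-90 item responses from latent traits
#'
#' Each of the 55 items belongs to one subscale; its response is a graded
#' ordinal cut of `trait + item noise`, where the item noise is standard
#' normal and the cut points are `thresholds`. The map is monotone in the
#' trait, so each subscale's raw score correlates positively with its trait.
#'
#' @param traits Tibble from [generate_traits()].
#' @param thresholds Four increasing cut points on the latent (trait + noise)
#'   scale separating responses 1|2|3|4|5.
#' @param seed Integer seed.
#' @return A tibble with `participant_id` and integer columns
#'   `item_01` ... `item_55`, each in 1--5.
#' @examples
#' responses <- generate_scl90_responses(generate_traits(10, seed = 1), seed = 2)
#' @export
generate_scl90_responses <- function(traits,
                                     thresholds = c(-1.5, -0.5, 0.5, 1.5),
                                     seed = 1) {
  if (!all(.dim_codes %in% names(traits))) {
    abort("`traits` must contain the six dimension columns (int, dep, anx, hos, pho, psy).")
  }
  if (length(thresholds) != 4 || is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be four strictly increasing cut points.")
  }
  n <- nrow(traits)
  item_dims <- scl90_item_map()$dimension
  if (n == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character()), rep(list(integer()), 55)),
      c("participant_id", .item_cols())
    ))
    return(out)
  }
  set.seed(seed)
  latent <- as.matrix(traits[, item_dims]) +
    matrix(rnorm(n * 55), n, 55)
  resp <- matrix(
    1L + findInterval(latent, thresholds),
    n, 55, dimnames = list(NULL, .item_cols())
  )
  dplyr::bind_cols(
    tibble::tibble(participant_id = traits$participant_id),
    tibble::as_tibble(resp)
  )
}
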