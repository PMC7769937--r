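#' Facial key-point schema
#'
#' The package tracks 36 facial key points (ids 0--35): six midline points and
#' fifteen mirrored left/right pairs placed near the facial features, in camera
#' space (metres) at a nominal 1.5 m capture distance. Point 0 (the nose tip)
#' is the per-frame coordinate reference that all other points are translated
#' against. The `dimension` column records which symptom dimension modulates a
#' point's motion amplitude in the synthetic cohort generator (`NA` for the
#' midline points, which carry no symptom signal).
#'
#' @return A tibble with columns `point_id` (0--35), `label`, `side`
#'   (`"left"`, `"right"`, `"mid"`), `anchor_x`, `anchor_y`, `anchor_z`
#'   (metres) and `dimension` (one of the six dimension codes or `NA`).
#' @examples
#' key_point_schema()
#' @export
key_point_schema <- function() {
  path <- system.file("extdata", "key_points.csv", package = "facemotion",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    point_id = readr::col_integer(),
                    label = readr::col_character(),
                    side = readr::col_character(),
                    anchor_x = readr::col_double(),
                    anchor_y = readr::col_double(),
                    anchor_z = readr::col_double(),
                    dimension = readr::col_character()
                  ))
}

#' The six SCL-90 dimensions measured by the package
#'
#' Item counts follow the instrument's subscale structure: 9 (interpersonal
#' sensitivity), 13 (depression), 10 (anxiety), 6 (hostility), 7 (phobic
#' anxiety) and 10 (psychoticism) five-point Likert items, 55 in total.
#'
#' @return A tibble with columns `dimension` (code), `label`, `n_items`,
#'   `score_min` and `score_max` (the attainable raw-score interval).
#' @examples
#' scl90_dimensions()
#' @export
scl90_dimensions <- function() {
  map <- .scl90_item_list()
  tibble::tibble(
    dimension = vapply(map$dimensions, `[[`, "", "code"),
    label = vapply(map$dimensions, `[[`, "", "label"),
    n_items = vapply(map$dimensions, function(d) as.integer(d$n_items), 1L)
  ) |>
    dplyr::mutate(
      score_min = .data$n_items * 1L,
      score_max = .data$n_items * 5L
    )
}

#' Item-to-subscale map for the 55 measured SCL-90 items
#'
#' Item ids are subscale-local (`item_01` ... `item_55` in canonical dimension
#' order); the instrument's original 90-item numbering is not modelled.
#'
#' @return A tibble with columns `item` and `dimension`.
#' @export
scl90_item_map <- function() {
  map <- .scl90_item_list()
  purrr::map_dfr(map$dimensions, function(d) {
    tibble::tibble(item = unlist(d$items), dimension = d$code)
  })
}

#' Screening threshold on the six-subscale total score
#'
#' A factor score (raw subscale score divided by its item count) of at least 2
#' on every subscale flags negative mental-health symptoms; summed over the 55
#' measured items this puts the group threshold on the six-subscale total at
#' 2 x 55 = 110 points.
#'
#' @return A single integer, the total-score threshold.
#' @examples
#' scl90_threshold() # 110
#' @export
scl90_threshold <- function() {
  2L * sum(scl90_dimensions()$n_items)
}

.scl90_item_list <- function() {
  path <- system.file("extdata", "scl90_items.json", package = "facemotion",
                      mustWork = TRUE)
  jsonlite::read_json(path)
}

.item_cols <- function() sprintf("item_%02d", 1:55)
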