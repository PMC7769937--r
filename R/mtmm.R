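.mtmm_vars <- function() {
  paste0(rep(toupper(.dim_codes), 2), rep(c("1", "2"), each = 6))
}

.mtmm_trait <- function(v) tolower(substr(v, 1, 3))
.mtmm_method <- function(v) {
  ifelse(substr(v, 4, 4) == "1", "model", "scale")
}

#' Multitrait-multimethod matrix of predictions and scores
#'
#' Builds the 12 x 12 Pearson correlation matrix over the six whole-data
#' model predictions (`INT1` ... `PSY1`) and the six actual raw subscale
#' scores (`INT2` ... `PSY2`). The monotrait-heteromethod entries (the
#' validity diagonal) carry convergent-validity evidence; the two
#' heterotrait-monomethod triangles are the within-method correlations the
#' discriminant assessment compares against.
#'
#' @inheritParams criterion_validity
#' @return A 12 x 12 matrix of class `mtmm_matrix`.
#' @export
mtmm_matrix <- function(predictions, scores) {
  predictions <- .as_predictions(predictions)
  whole <- .pred_wide(predictions, "whole")
  actual <- .scores_wide(scores)
  if (!identical(whole$participant_id, actual$participant_id)) {
    abort("predictions and scores cover different participants.")
  }
  m <- cbind(as.matrix(whole[, .dim_codes]), as.matrix(actual[, .dim_codes]))
  colnames(m) <- .mtmm_vars()
  as_mtmm(cor(m))
}

#' Validate a 12 x 12 matrix as an MTMM matrix
#'
#' @param m A numeric 12 x 12 correlation matrix; row/column names, when
#'   present, must be `INT1 ... PSY1, INT2 ... PSY2`.
#' @return The matrix with class `mtmm_matrix`.
#' @export
as_mtmm <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(12, 12))) abort("an MTMM matrix must be 12 x 12.")
  if (is.null(rownames(m))) {
    dimnames(m) <- list(.mtmm_vars(), .mtmm_vars())
  }
  if (!identical(rownames(m), .mtmm_vars()) ||
      !identical(colnames(m), .mtmm_vars())) {
    abort(sprintf("MTMM variables must be %s.",
                  paste(.mtmm_vars(), collapse = ", ")))
  }
  if (max(abs(m - t(m))) > 1e-8) abort("an MTMM matrix must be symmetric.")
  if (max(abs(diag(m) - 1)) > 1e-8) abort("an MTMM matrix must have a unit diagonal.")
  if (any(m < -1 - 1e-8 | m > 1 + 1e-8)) {
    abort("MTMM entries must lie in [-1, 1].")
  }
  structure(m, class = c("mtmm_matrix", "matrix", "array"))
}

#' Read an externally supplied MTMM matrix
#'
#' Reads a CSV whose first column (`variable`) holds the row labels
#' `INT1 ... PSY2` and whose remaining 12 columns hold the correlations.
#' The package ships such a file,
#' `system.file("extdata", "reference_mtmm.csv", package = "facemotion")`,
#' holding the matrix reported by a published facial-movement study of the
#' same six dimensions, usable as a worked example for the convergent and
#' discriminant assessments.
#'
#' @param path Path to the CSV.
#' @return A `mtmm_matrix`.
#' @export
read_mtmm <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  as_mtmm(m)
}

#' Validity diagonal of an MTMM matrix
#'
#' @param m A `mtmm_matrix`.
#' @return A tibble with `dimension` and `r` (the monotrait-heteromethod
#'   correlation).
#' @export
validity_diagonal <- function(m) {
  m <- as_mtmm(m)
  tibble::tibble(
    dimension = factor(.dim_codes, levels = .dim_codes),
    r = m[cbind(paste0(toupper(.dim_codes), "1"),
                paste0(toupper(.dim_codes), "2"))]
  )
}

#' Tidy an MTMM matrix into labelled pairs
#'
#' @param x A `mtmm_matrix`.
#' @param ... Unused.
#' @return A tibble of the 66 unordered variable pairs: `var1`, `var2`,
#'   `trait1`, `trait2`, `method1`, `method2`, `r`, and `block` (one of
#'   `monotrait_heteromethod`, `heterotrait_monomethod`,
#'   `heterotrait_heteromethod`).
#' @export
tidy.mtmm_matrix <- function(x, ...) {
  vars <- .mtmm_vars()
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = vars[pairs[, "row"]],
    var2 = vars[pairs[, "col"]],
    r = x[pairs]
  ) |>
    dplyr::mutate(
      trait1 = .mtmm_trait(.data$var1),
      trait2 = .mtmm_trait(.data$var2),
      method1 = .mtmm_method(.data$var1),
      method2 = .mtmm_method(.data$var2),
      block = dplyr::case_when(
        .data$trait1 == .data$trait2 & .data$method1 != .data$method2 ~
          "monotrait_heteromethod",
        .data$trait1 != .data$trait2 & .data$method1 == .data$method2 ~
          "heterotrait_monomethod",
        TRUE ~ "heterotrait_heteromethod"
      )
    ) |>
    dplyr::select("var1", "var2", "trait1", "trait2", "method1", "method2",
                  "r", "block")
  out
}

#' Convergent-validity assessment
#'
#' A trait passes when its validity-diagonal entry strictly exceeds every
#' heterotrait-heteromethod correlation in its row and column of the
#' between-method block (different-trait, different-method pairs involving
#' that trait). The margin is the diagonal entry minus the strongest
#' competitor.
#'
#' @param m A `mtmm_matrix`.
#' @return A tibble with `dimension`, `validity_r`, `max_competitor`,
#'   `margin`, `pass`.
#' @export
assess_convergent <- function(m) {
  .assess_block(m, "heterotrait_heteromethod")
}

#' Discriminant-validity assessment
#'
#' A trait passes when its validity-diagonal entry strictly exceeds every
#' heterotrait-monomethod correlation involving that trait in both
#' within-method triangles.
#'
#' @inheritParams assess_convergent
#' @return A tibble with `dimension`, `validity_r`, `max_competitor`,
#'   `margin`, `pass`.
#' @export
assess_discriminant <- function(m) {
  .assess_block(m, "heterotrait_monomethod")
}

.assess_block <- function(m, competing_block) {
  m <- as_mtmm(m)
  pairs <- tidy.mtmm_matrix(m)
  diag_tbl <- validity_diagonal(m)
  purrr::map_dfr(.dim_codes, function(d) {
    competitors <- pairs |>
      dplyr::filter(.data$block == competing_block,
                    .data$trait1 == d | .data$trait2 == d)
    max_comp <- max(competitors$r)
    diag_r <- diag_tbl$r[diag_tbl$dimension == d]
    tibble::tibble(
      dimension = d,
      validity_r = diag_r,
      max_competitor = max_comp,
      margin = diag_r - max_comp,
      pass = diag_r > max_comp
    )
  }) |>
    dplyr::mutate(dimension = factor(.data$dimension, levels = .dim_codes))
}

#' Full psychometric evaluation of a fitted model set
#'
#' Bundles split-half reliability, criterion validity, the MTMM matrix and
#' the convergent/discriminant verdicts into one object.
#'
#' @inheritParams criterion_validity
#' @return A list of class `psychometric_eval` with elements `reliability`,
#'   `validity`, `mtmm`, `convergent`, `discriminant`.
#' @export
evaluate_models <- function(predictions, scores) {
  predictions <- .as_predictions(predictions)
  m <- mtmm_matrix(predictions, scores)
  structure(
    list(
      reliability = split_half_reliability(predictions),
      validity = criterion_validity(predictions, scores),
      mtmm = m,
      convergent = assess_convergent(m),
      discriminant = assess_discriminant(m)
    ),
    class = "psychometric_eval"
  )
}

#' @export
print.psychometric_eval <- function(x, ...) {
  cat("Psychometric evaluation of facial symptom-prediction models\n\n")
  tab <- x$reliability |>
    dplyr::select("dimension", "r1") |>
    dplyr::left_join(dplyr::select(x$validity, "dimension", "r2"),
                     by = "dimension") |>
    dplyr::left_join(dplyr::select(x$convergent, "dimension",
                                   convergent = "pass"), by = "dimension") |>
    dplyr::left_join(dplyr::select(x$discriminant, "dimension",
                                   discriminant = "pass"), by = "dimension")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-26s R1 = %6.3f  R2 = %6.3f  convergent: %-5s discriminant: %s\n",
                .dim_labels[as.character(tab$dimension[i])],
                tab$r1[i], tab$r2[i],
                ifelse(tab$convergent[i], "pass", "fail"),
                ifelse(tab$discriminant[i], "pass", "fail")))
  }
  invisible(x)
}

#' Tidy a psychometric evaluation
#'
#' @param x A `psychometric_eval`.
#' @param ... Unused.
#' @return A per-dimension tibble: `dimension`, `r1`, `r2`, `validity_r`,
#'   `convergent`, `discriminant`.
#' @export
tidy.psychometric_eval <- function(x, ...) {
  x$reliability |>
    dplyr::select("dimension", "r1", r1_p = "p") |>
    dplyr::left_join(dplyr::select(x$validity, "dimension", "r2",
                                   r2_p = "p"), by = "dimension") |>
    dplyr::left_join(dplyr::select(x$convergent, "dimension", "validity_r",
                                   convergent = "pass"), by = "dimension") |>
    dplyr::left_join(dplyr::select(x$discriminant, "dimension",
                                   discriminant = "pass"), by = "dimension")
}

#' One-row summary of a psychometric evaluation
#'
#' @param x A `psychometric_eval`.
#' @param ... Unused.
#' @return A one-row tibble: reliability and validity ranges plus the
#'   numbers of convergent and discriminant passes.
#' @export
glance.psychometric_eval <- function(x, ...) {
  tibble::tibble(
    r1_min = min(x$reliability$r1),
    r1_max = max(x$reliability$r1),
    r2_min = min(x$validity$r2),
    r2_max = max(x$validity$r2),
    n_convergent_pass = sum(x$convergent$pass),
    n_discriminant_pass = sum(x$discriminant$pass)
  )
}

#' Steiger's z test for dependent correlations
#'
#' Tests whether two correlations sharing one variable (r(j,k) vs r(j,h),
#' measured on the same participants) differ. Offered as an inferential
#' companion to the strict-dominance convergent/discriminant rules, which
#' deliberately use no test; it does not drive the default verdicts.
#'
#' @param r_jk,r_jh The two dependent correlations being compared.
#' @param r_kh The correlation between the two non-shared variables.
#' @param n Sample size.
#' @return A one-row tibble with `z` and the two-sided `p`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4) abort("Steiger's test needs n >= 4.")
  r_bar <- (r_jk + r_jh) / 2
  s <- (r_kh * (1 - 2 * r_bar^2) -
          0.5 * r_bar^2 * (1 - 2 * r_bar^2 - r_kh^2)) / (1 - r_bar^2)^2
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * s))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}
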