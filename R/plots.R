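#' Heatmap of an MTMM matrix
#'
#' Tile plot of the 12 x 12 correlation matrix with the validity diagonal
#' outlined, the standard visual for judging convergent and discriminant
#' validity.
#'
#' @param object A `mtmm_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtmm_matrix <- function(object, ...) {
  vars <- .mtmm_vars()
  df <- tidy.mtmm_matrix(object)
  df <- dplyr::bind_rows(
    df,
    dplyr::rename(df, var1 = "var2", var2 = "var1"),
    tibble::tibble(var1 = vars, var2 = vars, r = 1,
                   block = "diagonal")
  )
  df$var1 <- factor(df$var1, levels = vars)
  df$var2 <- factor(df$var2, levels = rev(vars))
  validity <- df$block == "monotrait_heteromethod"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(data = df[validity, ], color = "black",
                       linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Multitrait-multimethod matrix",
                  subtitle = "Outlined cells: validity diagonal (same trait, different method)") +
    ggplot2::theme_minimal()
}

#' Reliability and validity per dimension
#'
#' Dot plot of the split-half reliability (R1) and criterion validity (R2)
#' of the six models.
#'
#' @param object A `psychometric_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$reliability |>
      dplyr::transmute(.data$dimension, statistic = "R1 (split-half reliability)",
                       value = .data$r1),
    object$validity |>
      dplyr::transmute(.data$dimension, statistic = "R2 (criterion validity)",
                       value = .data$r2)
  )
  df$label <- .dim_labels[as.character(df$dimension)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$label,
                                   color = .data$statistic)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Pearson correlation", y = NULL, color = NULL,
                  title = "Model reliability and validity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Facial laterality of the selected features
#'
#' Counts, per dimension, how many of the selected feature columns belong
#' to left-face, right-face and midline key points. With a left-lateralised
#' motion signal the left side should be over-represented relative to its
#' 15/36 share of the points.
#'
#' @param fit A `symptom_models` object (or its `selection` tibble).
#' @return A ggplot object.
#' @export
plot_selected_sides <- function(fit) {
  selection <- if (inherits(fit, "symptom_models")) fit$selection else fit
  schema <- key_point_schema()
  df <- selection |>
    dplyr::mutate(
      point_id = as.integer(substr(.data$column, 6, 7)),
      side = schema$side[match(.data$point_id, schema$point_id)]
    ) |>
    dplyr::count(.data$dimension, .data$side)
  df$label <- .dim_labels[as.character(df$dimension)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "selected features",
                  fill = "face side",
                  title = "Laterality of selected features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
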