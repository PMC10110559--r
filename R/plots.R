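#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA score plot
#'
#' Scatter plot of the first two principal components of the regions,
#' optionally coloured by a region annotation (morphology, mucin or
#' stroma group).
#'
#' @param object A [gag_pca()] result.
#' @param colour_by Optional tibble with columns `region` and `group`
#'   (e.g. from [derive_groups()]) used to colour the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gag_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) {
    df <- dplyr::left_join(df, colour_by, by = "region")
  }
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Clustered heatmap of a quantification matrix
#'
#' Tile plot of the dendrogram-ordered, feature-wise z-scored display
#' matrix produced by [heatmap_order()].
#'
#' @param ho A [heatmap_order()] result.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(ho) {
  disp <- tibble::as_tibble(ho$display, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "region",
                        values_to = "z") |>
    dplyr::mutate(feature = factor(.data$feature, levels = ho$row_order),
                  region = factor(.data$region, levels = ho$col_order))
  ggplot2::ggplot(disp, ggplot2::aes(x = .data$region, y = .data$feature,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar plot of a sulfation summary statistic by group
#'
#' @param summaries Output of [summarize_profiles()] joined to a `group`
#'   column (as written by [run_pipeline()]).
#' @param metric One of the summary columns, e.g. `"total_pmol"`,
#'   `"avg_sulfation"`, `"ratio_6s4s"`, `"no_total"`.
#' @return A ggplot object (group means with SD error bars, faceted by
#'   GAG class).
#' @export
plot_sulfation_summary <- function(summaries, metric = "total_pmol") {
  stopifnot(metric %in% names(summaries), "group" %in% names(summaries))
  df <- summaries |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group, .data$gag_class) |>
    dplyr::summarise(
      mean = mean(.data[[metric]], na.rm = TRUE),
      sd = stats::sd(.data[[metric]], na.rm = TRUE),
      .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~gag_class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
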