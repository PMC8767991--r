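#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Before-vs-during scatter of code-group frequencies
#'
#' Log-log scatter of each code grouping's early-period count against its
#' late-period count, colored by variation index. The identity diagonal
#' marks groupings used equally often in both periods; points above it
#' increased, points below decreased.
#'
#' @param object A `variation_table`.
#' @param label_top Label the `label_top` groupings with the largest
#'   variation index (0 for none).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variation_table
#' @export
autoplot.variation_table <- function(object, label_top = 5, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$n_early > 0 & df$n_late > 0, ]
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$n_early, y = .data$n_late, color = .data$vi)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_viridis_c(name = "Variation\nindex") +
    ggplot2::labs(
      x = sprintf("Codes in %s", attr(object, "periods")[1]),
      y = sprintf("Codes in %s", attr(object, "periods")[2])
    ) +
    ggplot2::theme_minimal()
  if (label_top > 0 && nrow(df) > 0) {
    lab <- df[order(-df$vi), ][seq_len(min(label_top, nrow(df))), ]
    lab$short <- sub(".*\\(([^)]+)\\)$", "\\1", lab$group)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = .data$short),
      vjust = -0.8, size = 3, show.legend = FALSE
    )
  }
  p
}

#' Cumulative frequency of the most-used code groupings
#'
#' Ranked bar-and-line view of a frequency matrix: bars give each
#' grouping's share of all code occurrences, the line their cumulative
#' share.
#'
#' @param object A `freq_matrix`.
#' @param k Number of top groupings shown (default 21).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot freq_matrix
#' @export
autoplot.freq_matrix <- function(object, k = 21, ...) {
  tk <- top_k(object, k)
  tk$short <- sub(".*\\(([^)]+)\\)$", "\\1", tk$group)
  tk$short <- factor(tk$short, levels = tk$short)
  ggplot2::ggplot(tk, ggplot2::aes(x = .data$short)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$share_pct), fill = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$cum_share_pct, group = 1),
      color = "firebrick"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$cum_share_pct),
      color = "firebrick", size = 1
    ) +
    ggplot2::labs(
      x = NULL, y = "Share of code occurrences (%)",
      title = sprintf(
        "Top %d groupings, aggregation level %d",
        nrow(tk), attr(object, "level")
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
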