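#' Volcano plot of a contrast
#'
#' Log2 fold change against -log10 p, colored by DEG status, with the
#' calling thresholds drawn as reference lines.
#'
#' @param object A `treg_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot treg_contrast
#' @export
autoplot.treg_contrast <- function(object, ...) {
  th <- attr(object, "thresholds") %||% deg_thresholds()
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-th$fc_threshold, th$fc_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(th$p_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p",
                  colour = NULL,
                  title = attr(object, "dataset_id")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of up/down DEG counts per dataset
#'
#' @param summaries Tibble of [deg_summary()] rows.
#' @return A ggplot object.
#' @export
plot_deg_summary <- function(summaries) {
  df <- summaries |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset_id, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "DEGs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat-style tile plot of decomposition percentages
#'
#' @param rows Tibble from [decompose_suite()].
#' @param value Column to fill by (default `"pct_up"`).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(rows, value = "pct_up") {
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$catalog, y = .data$dataset_id,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data[[value]]), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot-and-errorbar plot of a group comparison
#'
#' @param comparison A `group_comparison`.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(comparison) {
  g <- comparison$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$condition_group, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::labs(
      x = NULL, y = comparison$metric,
      subtitle = sprintf("%s, %s vs rest: p = %.4g",
                         comparison$test$method,
                         comparison$test$focus_group,
                         comparison$test$p_value)
    ) +
    ggplot2::theme_minimal()
}
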