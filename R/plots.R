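#' @export
autoplot.psd_estimate <- function(object, channels = NULL, log_power = TRUE, ...) {
  channels <- channels %||% object$channel_labels
  tab <- tidyr::expand_grid(channel = object$channel_labels,
                            freq = object$freq)
  tab$psd <- as.vector(t(object$psd))
  tab <- filter(tab, .data$channel %in% channels)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$freq, y = .data$psd,
                                         colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.dtf_result <- function(object, band = c(4, 8), ...) {
  tab <- tidy(object, band = band)
  tab$sink <- factor(tab$sink, levels = rev(object$channel_labels))
  tab$source <- factor(tab$source, levels = object$channel_labels)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$source, y = .data$sink,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "source channel j", y = "sink channel i",
                  fill = "DTF",
                  title = sprintf("Band-averaged DTF (%g-%g Hz)", band[1], band[2])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Band-power comparison plot
#'
#' Channel-averaged power per band (optionally split by group), mirroring the
#' band-comparison panels of the analysis report.
#'
#' @param band_power_tab Tibble with columns `subject`, `band` and a power
#'   column.
#' @param value_col Power column to plot (default `"p_wm"`).
#' @param groups Optional tibble `subject`/`analysis_group` to facet by group.
#' @return A ggplot object.
#' @export
plot_band_power <- function(band_power_tab, value_col = "p_wm", groups = NULL) {
  tab <- band_power_tab |>
    group_by(.data$subject, .data$band) |>
    summarise(value = mean(.data[[value_col]]), .groups = "drop")
  if (!is.null(groups)) tab <- left_join(tab, groups, by = "subject")
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$band, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = value_col) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) p <- p + ggplot2::facet_wrap(~analysis_group)
  p
}

#' Node-strength topography as a bar chart
#'
#' @param dtf_i_tab Tibble with columns `channel` and `value` (per-channel
#'   node connectivity), optionally `subject` (then averaged).
#' @param regions Region map used to colour channels.
#' @return A ggplot object.
#' @export
plot_node_strength <- function(dtf_i_tab, regions = default_region_map(unique(dtf_i_tab$channel))) {
  tab <- dtf_i_tab |>
    group_by(.data$channel) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    left_join(regions, by = "channel")
  tab$channel <- factor(tab$channel, levels = tab$channel[order(-tab$value)])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$channel, y = .data$value,
                                    fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "node DTF strength", fill = "region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
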