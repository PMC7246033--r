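# Figure builders. Timepoint colours follow the blue/yellow/red convention
# for 12/24/48 h used throughout the assay's figures.

timepoint_palette <- function() {
  c("12" = "#2c5aa0", "24" = "#e0b000", "48" = "#c03030")
}

#' Line graph of percent changes over culture time
#'
#' One line per antibody, percent change against culture time, facetted by
#' functional category when the changes carry one.
#'
#' @param changes Changes tibble with `antibody`, `timepoint_h`, `delta_pct`
#'   and optionally `category_label`.
#' @param categories Optional subset of categories to show.
#' @return A ggplot.
#' @export
plot_group_lines <- function(changes, categories = NULL) {
  changes <- tibble::as_tibble(changes)
  if (!is.null(categories)) {
    changes <- changes[changes$category_label %in% categories, ]
  }
  p <- ggplot2::ggplot(changes, ggplot2::aes(
    x = .data$timepoint_h, y = .data$delta_pct, group = .data$antibody
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(breaks = TIMEPOINTS_H) +
    ggplot2::labs(x = "Culture time (h)", y = "Expression change (%)") +
    ggplot2::theme_minimal()
  if ("category_label" %in% names(changes) && any(!is.na(changes$category_label))) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$category_label))
  }
  p
}

#' Star (radar) plot of one category
#'
#' Antibodies of the category in fixed panel order around the circle, one
#' ring per timepoint (identical antibody order across rings).
#'
#' @inheritParams build_group_series
#' @return A ggplot in polar coordinates.
#' @export
plot_star <- function(changes, panel, category) {
  series <- build_group_series(changes, panel, category)
  long <- series |>
    tidyr::pivot_longer(
      dplyr::all_of(paste0("t", TIMEPOINTS_H)),
      names_to = "timepoint_h", values_to = "delta_pct"
    ) |>
    dplyr::mutate(timepoint_h = factor(sub("^t", "", .data$timepoint_h), levels = TIMEPOINTS_H)) |>
    dplyr::filter(!is.na(.data$delta_pct)) |>
    dplyr::mutate(antibody = factor(.data$antibody, levels = unique(series$antibody)))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$antibody, y = .data$delta_pct,
    colour = .data$timepoint_h, group = .data$timepoint_h
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::scale_colour_manual(values = timepoint_palette(), name = "Time (h)") +
    ggplot2::labs(x = NULL, y = "Expression change (%)", title = category) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' Dot plot of highly up- and down-regulated antibodies
#'
#' @param dot_data Output of [build_dot_plot_data()].
#' @return A ggplot with up- and down-regulated panels.
#' @export
plot_dot_changes <- function(dot_data) {
  dot_data <- tibble::as_tibble(dot_data)
  dot_data <- dot_data[dot_data$direction != "none", ]
  dot_data$antibody <- factor(dot_data$antibody, levels = rev(unique(dot_data$antibody)))
  ggplot2::ggplot(dot_data, ggplot2::aes(
    x = .data$delta_pct, y = .data$antibody,
    colour = factor(.data$timepoint_h, levels = TIMEPOINTS_H)
  )) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = timepoint_palette(), name = "Time (h)") +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction), scales = "free") +
    ggplot2::labs(x = "Expression change (%)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
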