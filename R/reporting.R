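# Reporting: figure-ready data reductions and machine-readable exports.
#
# Three reductions mirror the assay's standard figures: per-category line
# series over 12/24/48 h, per-timepoint star (radar) rings in fixed panel
# order, and up/down dot plots of the highly changed antibodies (>10 points).

TIMEPOINTS_H <- c(12, 24, 48)

#' Build a category's line-graph series
#'
#' One series per entry of the category -- primaries first, then overlap
#' references resolved to their primary measurement -- with the percent
#' change at each of the 12/24/48 h timepoints (`NA` where a timepoint was
#' not analysed). The builder is pure: it selects and orders, never
#' modifies, the change values.
#'
#' @param changes Changes tibble (from [run_expression_pipeline()] or
#'   [tidy()] of its result) with `antibody`, `timepoint_h`, `delta_pct`.
#' @param panel An `ip_panel`.
#' @param category Category label present in the panel.
#' @return Tibble `category`, `antibody`, `is_overlap`, `t12`, `t24`, `t48`.
#' @export
build_group_series <- function(changes, panel, category) {
  stopifnot(inherits(panel, "ip_panel"))
  entries <- panel_entries(panel, category)
  changes <- tibble::as_tibble(changes)
  wide <- tibble::tibble(antibody = entries$name, is_overlap = entries$is_overlap)
  for (tp in TIMEPOINTS_H) {
    at_tp <- changes[!is.na(changes$timepoint_h) & changes$timepoint_h == tp, ]
    wide[[paste0("t", tp)]] <- at_tp$delta_pct[match(wide$antibody, at_tp$antibody)]
  }
  dplyr::bind_cols(tibble::tibble(category = category), wide)
}

#' Build the data behind the high-change dot plots
#'
#' Applies [filter_high_changes()] and returns one dot per (antibody,
#' timepoint) with its functional category and direction, ordered by panel
#' order then timepoint; the `direction` column gives the up/down panel
#' split.
#'
#' @inheritParams build_group_series
#' @param panel Optional `ip_panel` used for category annotation and
#'   ordering; without it, input order is kept.
#' @param threshold_pct Magnitude threshold in percent points (default 10).
#' @return Tibble `antibody`, `category`, `timepoint_h`, `delta_pct`,
#'   `direction`.
#' @export
build_dot_plot_data <- function(changes, panel = NULL, threshold_pct = 10) {
  high <- filter_high_changes(tibble::as_tibble(changes), threshold_pct)
  out <- tibble::tibble(
    antibody = high$antibody,
    category = if ("category_label" %in% names(high)) high$category_label else NA_character_,
    timepoint_h = high$timepoint_h,
    delta_pct = high$delta_pct
  )
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "ip_panel"))
    primaries <- panel[!panel$is_overlap, ]
    out$category <- primaries$category[match(out$antibody, primaries$name)]
    out <- out[order(match(out$antibody, primaries$name), out$timepoint_h), ]
  }
  out$direction <- if (nrow(out) > 0) change_direction(out$delta_pct) else
    factor(character(0), levels = c("down", "none", "up"))
  out
}

#' Export pipeline results to CSV files (and optionally figures)
#'
#' Writes `results.csv` (the per-antibody changes table), `group_series.csv`
#' (line-graph series for every panel category) and `dot_data.csv` (the
#' high-change dots). Re-export of identical inputs is byte-identical for
#' the CSVs; figures (`lines.png`, `star.png`, `dots.png`) are excluded from
#' that claim.
#'
#' @param result An `ip_result`.
#' @param dir Output directory (created if needed).
#' @param panel Optional `ip_panel` for the series/dot reductions; defaults
#'   to the packaged panel when every antibody is found there, otherwise the
#'   series export is skipped.
#' @param threshold_pct Dot-plot threshold, percent points.
#' @param figures Also write PNG figures (default `TRUE`).
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(result, dir, panel = NULL, threshold_pct = 10,
                           figures = TRUE) {
  stopifnot(inherits(result, "ip_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  changes <- result$changes
  files <- c(results = file.path(dir, "results.csv"))
  res_out <- changes
  res_out$band <- as.character(res_out$band)
  res_out$direction <- as.character(res_out$direction)
  readr::write_csv(res_out, files[["results"]], progress = FALSE)

  if (!is.null(panel)) {
    series <- purrr::map(
      attr(panel, "categories"),
      function(cat) build_group_series(changes, panel, cat)
    ) |> purrr::list_rbind()
    files[["group_series"]] <- file.path(dir, "group_series.csv")
    readr::write_csv(series, files[["group_series"]], progress = FALSE)
  }

  dots <- build_dot_plot_data(changes, panel = panel, threshold_pct = threshold_pct)
  dots$direction <- as.character(dots$direction)
  files[["dot_data"]] <- file.path(dir, "dot_data.csv")
  readr::write_csv(dots, files[["dot_data"]], progress = FALSE)

  if (figures && nrow(changes) > 0) {
    files[["lines"]] <- file.path(dir, "lines.png")
    ggplot2::ggsave(files[["lines"]], plot_group_lines(changes),
      width = 9, height = 6, dpi = 150
    )
    files[["dots"]] <- file.path(dir, "dots.png")
    ggplot2::ggsave(files[["dots"]], plot_dot_changes(dots),
      width = 7, height = 8, dpi = 150
    )
    if (!is.null(panel)) {
      first_cat <- attr(panel, "categories")[1]
      files[["star"]] <- file.path(dir, "star.png")
      ggplot2::ggsave(files[["star"]], plot_star(changes, panel, first_cat),
        width = 7, height = 7, dpi = 150
      )
    }
  }
  invisible(files)
}
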