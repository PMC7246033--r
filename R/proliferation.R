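# In situ proliferation index from paired cell counts.
#
# Cells are counted on the same photographed fields before and after a
# culture interval; the index expresses the growth (final - initial) as a
# percentage of the initial count and is averaged, unweighted, over the
# fields (typically 10 representative images per arm).

#' Per-field in situ proliferation index
#'
#' @param initial_count,final_count Non-negative integer cell counts;
#'   `initial_count` must be positive.
#' @return `100 * (final_count - initial_count) / initial_count`, in percent.
#' @examples
#' proliferation_index(100, 173) # 73
#' @export
proliferation_index <- function(initial_count, final_count) {
  if (any(!is.finite(initial_count)) || any(initial_count != round(initial_count)) ||
    any(!is.finite(final_count)) || any(final_count != round(final_count))) {
    stop_iphplc("cell counts must be finite integers")
  }
  if (any(final_count < 0)) stop_iphplc("final counts must be non-negative")
  if (any(initial_count <= 0)) {
    stop_iphplc("initial count must be positive to define a proliferation index")
  }
  100 * (final_count - initial_count) / initial_count
}

#' Summarise proliferation per arm and culture duration
#'
#' Averages the per-field indices (unweighted) and reports their spread as
#' the SD across fields, mirroring how the assay reports mean +/- dispersion
#' per arm.
#'
#' @param counts Tibble with columns `arm`, `field_id`, `duration_h`,
#'   `initial_count`, `final_count` (see [simulate_cell_counts()] for a
#'   generator).
#' @return Tibble per (arm, duration_h): `index_pct` (mean of field indices),
#'   `dispersion` (SD across fields), `n_fields`.
#' @export
summarize_proliferation <- function(counts) {
  counts <- tibble::as_tibble(counts)
  needed <- c("arm", "field_id", "duration_h", "initial_count", "final_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    stop_iphplc("counts table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  counts |>
    dplyr::mutate(index = proliferation_index(.data$initial_count, .data$final_count)) |>
    dplyr::group_by(.data$arm, .data$duration_h) |>
    dplyr::summarise(
      index_pct = mean(.data$index),
      dispersion = sd(.data$index),
      n_fields = dplyr::n(),
      .groups = "drop"
    )
}

#' Treated-minus-control proliferation difference
#'
#' @param treated,control One-row summaries (as from
#'   [summarize_proliferation()], or any list/tibble with `duration_h` and
#'   `index_pct`) for the same culture duration.
#' @return Percentage-point difference `treated - control`, rounded to one
#'   decimal as reported.
#' @examples
#' t24 <- tibble::tibble(arm = "treated", duration_h = 24, index_pct = 73.1)
#' c24 <- tibble::tibble(arm = "control", duration_h = 24, index_pct = 69.9)
#' index_difference(t24, c24) # 3.2
#' @export
index_difference <- function(treated, control) {
  get1 <- function(x, f) {
    v <- if (is.data.frame(x)) x[[f]] else x[[f]]
    if (length(v) != 1 || !is.finite(v)) stop_iphplc("`%s` must be a single finite value", f)
    v
  }
  if (get1(treated, "duration_h") != get1(control, "duration_h")) {
    stop_iphplc("treated and control summaries have different culture durations")
  }
  round(get1(treated, "index_pct") - get1(control, "index_pct"), 1)
}
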