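# Quantification: trace -> single expression level.
#
# Steps, in the order the assay applies them:
#   1. local linear baseline through the signal at the peak-window endpoints
#   2. trapezoidal integration over the window, minutes converted to seconds,
#      so areas come out in mAU*s
#   3. subtraction of the negative-control (nonspecific binding) peak area,
#      floored at zero
#   4. square root of the net area -> the expression level that is compared
#      between arms.

#' Define a peak integration window
#'
#' A fixed elution window shared across a cohort keeps sequentially run
#' control and treated samples comparable; no automatic peak detection is
#' attempted.
#'
#' @param start_min,end_min Window bounds in minutes, `start_min < end_min`.
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(start_min, end_min) {
  assert_finite_scalar(start_min, "start_min")
  assert_finite_scalar(end_min, "end_min")
  if (start_min >= end_min) stop_iphplc("peak window start must precede its end")
  structure(list(start_min = start_min, end_min = end_min), class = "peak_window")
}

#' @export
print.peak_window <- function(x, ...) {
  cat(sprintf("<peak_window> %.3f-%.3f min\n", x$start_min, x$end_min))
  invisible(x)
}

window_indices <- function(trace, window) {
  t <- trace$data$time_min
  if (window$start_min < t[1] - 1e-9 || window$end_min > t[length(t)] + 1e-9) {
    stop_iphplc(
      "peak window [%.3f, %.3f] lies outside the trace range [%.3f, %.3f]",
      window$start_min, window$end_min, t[1], t[length(t)]
    )
  }
  which(t >= window$start_min - 1e-12 & t <= window$end_min + 1e-12)
}

#' Baseline-correct a trace inside a peak window
#'
#' Subtracts, inside the window only, the straight line through the signal
#' values at the window's first and last grid points. A linear local baseline
#' removes constant offsets and linear drift exactly; it is the package's
#' single baseline model (`"linear-endpoints"`) and is isolated here so a
#' different model can be swapped in.
#'
#' @param trace An `hplc_trace`.
#' @param window A [peak_window()] within the trace's time range.
#' @return The corrected `hplc_trace`; values outside the window unchanged,
#'   with attribute `baseline_model` set.
#' @examples
#' tr <- hplc_trace(0:10, rep(5, 11), "Ki-67", "treated", 24, 1)
#' corrected <- correct_baseline(tr, peak_window(2, 8))
#' @export
correct_baseline <- function(trace, window) {
  if (!inherits(trace, "hplc_trace")) stop_iphplc("`trace` must be an hplc_trace")
  if (!inherits(window, "peak_window")) stop_iphplc("`window` must be a peak_window")
  idx <- window_indices(trace, window)
  if (length(idx) < 2) stop_iphplc("peak window contains fewer than 2 samples")
  t <- trace$data$time_min
  y <- trace$data$absorbance_mAU
  i1 <- idx[1]
  i2 <- idx[length(idx)]
  slope <- (y[i2] - y[i1]) / (t[i2] - t[i1])
  baseline <- y[i1] + slope * (t[idx] - t[i1])
  y[idx] <- y[idx] - baseline
  trace$data$absorbance_mAU <- y
  attr(trace, "baseline_model") <- "linear-endpoints"
  trace
}

#' Integrate a peak window to an area in mAU*s
#'
#' Trapezoidal integral of the absorbance over the window on the native time
#' grid, with minutes converted to seconds so the result carries the assay's
#' area unit (mAU*s). Values are integrated as-is (no rectification of
#' negative excursions).
#'
#' @inheritParams correct_baseline
#' @return Peak area in mAU*s.
#' @examples
#' tr <- hplc_trace(seq(0, 3, by = 0.05), rep(1, 61), "Ki-67", "treated", 24, 1)
#' integrate_window(tr, peak_window(1, 2)) # 60 mAU*s
#' @export
integrate_window <- function(trace, window) {
  if (!inherits(trace, "hplc_trace")) stop_iphplc("`trace` must be an hplc_trace")
  if (!inherits(window, "peak_window")) stop_iphplc("`window` must be a peak_window")
  idx <- window_indices(trace, window)
  if (length(idx) < 2) stop_iphplc("peak window contains fewer than 2 samples")
  t_s <- trace$data$time_min[idx] * 60
  y <- trace$data$absorbance_mAU[idx]
  n <- length(y)
  sum(diff(t_s) * (y[-1] + y[-n]) / 2)
}

#' Subtract the negative-control peak area
#'
#' The negative-control antibody's peak area estimates nonspecific binding
#' and is subtracted from each raw peak area. A subtraction that would go
#' negative is floored at zero and flagged (`clamped`), never propagated into
#' the square root.
#'
#' @param raw_area_mAU_s,negative_control_area_mAU_s Non-negative areas in
#'   mAU*s; vectors are recycled in the usual way.
#' @return Tibble with columns `net_area_mAU_s` and `clamped`.
#' @examples
#' net_peak_area(500, 100) # net 400, not clamped
#' net_peak_area(80, 100) # net 0, clamped
#' @export
net_peak_area <- function(raw_area_mAU_s, negative_control_area_mAU_s) {
  if (any(!is.finite(raw_area_mAU_s)) || any(raw_area_mAU_s < 0)) {
    stop_iphplc("raw peak areas must be finite and non-negative")
  }
  if (any(!is.finite(negative_control_area_mAU_s)) || any(negative_control_area_mAU_s < 0)) {
    stop_iphplc("negative-control areas must be finite and non-negative")
  }
  net <- pmax(raw_area_mAU_s - negative_control_area_mAU_s, 0)
  tibble::tibble(
    net_area_mAU_s = net,
    clamped = raw_area_mAU_s < negative_control_area_mAU_s
  )
}

#' Expression level from a net peak area
#'
#' Expression levels are compared on the square-root scale of the net peak
#' area, which compresses ratios: a level ratio equals the square root of the
#' corresponding area ratio.
#'
#' @param net_area_mAU_s Non-negative net peak area(s), mAU*s.
#' @return `sqrt(net_area_mAU_s)`, in sqrt(mAU*s).
#' @examples
#' expression_level(400) # 20
#' @export
expression_level <- function(net_area_mAU_s) {
  if (any(!is.finite(net_area_mAU_s)) || any(net_area_mAU_s < 0)) {
    stop_iphplc("net areas must be finite and non-negative (clamp upstream)")
  }
  sqrt(net_area_mAU_s)
}

get_manifest_trace <- function(manifest, i) {
  if ("trace" %in% names(manifest)) {
    tr <- manifest$trace[[i]]
    if (inherits(tr, "hplc_trace")) return(tr)
  }
  if ("path" %in% names(manifest)) return(read_trace(manifest$path[i]))
  stop_iphplc("manifest must carry a `trace` list-column or a `path` column")
}

#' Quantify every trace of a cohort into a peak-area table
#'
#' Applies baseline correction, window integration, replicate-matched
#' negative-control subtraction and the square-root transform to each trace
#' listed in a manifest.
#'
#' @param manifest Tibble with identity columns `antibody`, `arm`,
#'   `timepoint_h`, `replicate` and either a `trace` list-column of
#'   [hplc_trace()] objects or a `path` column of trace files (see
#'   [read_manifest()]).
#' @param window The cohort's shared [peak_window()].
#' @param per_antibody_negative If `TRUE`, negative-control traces are matched
#'   to samples by antibody as well as replicate; by default a single shared
#'   negative-control channel per replicate is used.
#' @return Tibble with one row per treated/control trace: identity columns,
#'   `raw_area_mAU_s`, `neg_area_mAU_s`, `net_area_mAU_s`, `level`, `clamped`,
#'   and `baseline_model`.
#' @export
quantify_cohort <- function(manifest, window, per_antibody_negative = FALSE) {
  manifest <- tibble::as_tibble(manifest)
  needed <- c("antibody", "arm", "timepoint_h", "replicate")
  missing <- setdiff(needed, names(manifest))
  if (length(missing) > 0) {
    stop_iphplc("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  }
  raw <- vapply(seq_len(nrow(manifest)), function(i) {
    tr <- get_manifest_trace(manifest, i)
    integrate_window(correct_baseline(tr, window), window)
  }, numeric(1))

  areas <- manifest[needed]
  areas$raw_area_mAU_s <- raw

  neg <- areas[areas$arm == "negative_control", ]
  smp <- areas[areas$arm != "negative_control", ]
  if (nrow(neg) == 0) {
    warning("cohort has no negative-control traces; assuming zero nonspecific area")
    smp$neg_area_mAU_s <- 0
  } else {
    key_cols <- if (per_antibody_negative) c("antibody", "replicate") else "replicate"
    neg_tab <- neg |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
      dplyr::summarise(neg_area_mAU_s = mean(.data$raw_area_mAU_s), .groups = "drop")
    smp <- dplyr::left_join(smp, neg_tab, by = key_cols)
    if (any(is.na(smp$neg_area_mAU_s))) {
      # replicates without their own negative channel fall back to the cohort mean
      smp$neg_area_mAU_s[is.na(smp$neg_area_mAU_s)] <- mean(neg$raw_area_mAU_s)
    }
  }
  nets <- net_peak_area(smp$raw_area_mAU_s, smp$neg_area_mAU_s)
  smp$net_area_mAU_s <- nets$net_area_mAU_s
  smp$clamped <- nets$clamped
  smp$level <- expression_level(smp$net_area_mAU_s)
  smp$baseline_model <- "linear-endpoints"
  smp
}
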