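# Expression pipeline: per-replicate levels -> the assay's headline numbers.
#
# percent_level = 100 * treated level / control level (replicate-paired),
# rescaled per sample so the housekeeping proteins read ~100 % ("proportional
# basal line"), then aggregated over 2-6 replicates with population SD, SEM
# s = sqrt(sigma^2 / n), a QC flag (SD <= 5 points), and a change band:
# minimal (<=5), slight (5-10), meaningful (10-20), marked (>20) percent.

#' Pipeline configuration
#'
#' @param band_edges Ascending band edges (percent points) separating
#'   minimal/slight/meaningful/marked changes; boundary values fall in the
#'   lower band.
#' @param qc_sd_max Replicate SD (percentage points) above which an antibody's
#'   measurement fails QC.
#' @param housekeeping Antibody names used as the proportional baseline.
#' @param hk_tolerance_pct Per-protein |change| (percent points) every
#'   housekeeping antibody must stay under after rescaling for the adjustment
#'   to be within tolerance.
#' @param variance `"population"` (default; SEM = sqrt(sigma^2/n) with the
#'   population sigma^2) or `"sample"` (n-1 denominator).
#' @param max_replicates Replicate count above which a warning is issued
#'   (measurements are still used).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band_edges = c(5, 10, 20),
                            qc_sd_max = 5,
                            housekeeping = housekeeping_antibodies(),
                            hk_tolerance_pct = 5,
                            variance = c("population", "sample"),
                            max_replicates = 6L) {
  if (length(band_edges) != 3 || is.unsorted(band_edges, strictly = TRUE) || any(band_edges <= 0)) {
    stop_iphplc("`band_edges` must be 3 strictly increasing positive numbers")
  }
  structure(
    list(
      band_edges = band_edges,
      qc_sd_max = qc_sd_max,
      housekeeping = housekeeping,
      hk_tolerance_pct = hk_tolerance_pct,
      variance = match.arg(variance),
      max_replicates = as.integer(max_replicates)
    ),
    class = "pipeline_config"
  )
}

#' Percent expression level of treated versus control
#'
#' @param treated_level,control_level Square-root-scale expression levels.
#' @return `100 * treated_level / control_level`.
#' @examples
#' expression_ratio(22, 20) # 110
#' @export
expression_ratio <- function(treated_level, control_level) {
  if (any(!is.finite(treated_level)) || any(!is.finite(control_level))) {
    stop_iphplc("expression levels must be finite")
  }
  if (any(control_level <= 0)) {
    stop_iphplc("control level is zero: failed control immunoprecipitation, ratio undefined")
  }
  100 * treated_level / control_level
}

#' Proportional housekeeping baseline adjustment
#'
#' Multiplies every percent level of one sample by `k = 100 / mean(percent
#' levels of the housekeeping antibodies)`, so the housekeeping mean is
#' exactly 100 afterwards. The per-protein tolerance (each housekeeping
#' |change| below `tolerance_pct`) is then *verified*, not forced: a
#' heterogeneous housekeeping set keeps `within_tolerance = FALSE`.
#'
#' @param levels Tibble with columns `antibody` and `percent_level` (extra
#'   columns pass through), or a named numeric vector of percent levels.
#' @param housekeeping Housekeeping antibody names; all must be present with
#'   positive levels.
#' @param tolerance_pct Per-protein tolerance, percent points (default 5).
#' @return List with `levels` (same shape as the input, rescaled) and
#'   `report`: a list with `scale_factor`, `housekeeping_deltas_after`
#'   (named, percent points) and `within_tolerance`.
#' @examples
#' x <- tibble::tibble(
#'   antibody = c("α-tubulin", "β-actin", "GAPDH", "Ki-67"),
#'   percent_level = c(104, 106, 105, 126)
#' )
#' adjust_housekeeping(x)$levels$percent_level[4] # 120
#' @export
adjust_housekeeping <- function(levels, housekeeping = housekeeping_antibodies(),
                                tolerance_pct = 5) {
  vec_in <- is.numeric(levels)
  if (vec_in) {
    levels <- tibble::tibble(antibody = names(levels), percent_level = as.numeric(levels))
  }
  levels <- tibble::as_tibble(levels)
  if (!all(c("antibody", "percent_level") %in% names(levels))) {
    stop_iphplc("`levels` needs columns `antibody` and `percent_level`")
  }
  hk_idx <- match(housekeeping, levels$antibody)
  if (anyNA(hk_idx)) {
    stop_iphplc(
      "housekeeping antibody missing from sample: %s",
      paste(housekeeping[is.na(hk_idx)], collapse = ", ")
    )
  }
  hk_levels <- levels$percent_level[hk_idx]
  if (any(!is.finite(hk_levels)) || any(hk_levels <= 0)) {
    stop_iphplc("housekeeping percent levels must be positive and finite")
  }
  k <- 100 / mean(hk_levels)
  levels$percent_level <- levels$percent_level * k
  deltas <- setNames(levels$percent_level[hk_idx] - 100, housekeeping)
  report <- list(
    scale_factor = k,
    housekeeping_deltas_after = deltas,
    within_tolerance = all(abs(deltas) < tolerance_pct)
  )
  out_levels <- if (vec_in) setNames(levels$percent_level, levels$antibody) else levels
  list(levels = out_levels, report = report)
}

#' Replicate mean, spread, SEM and QC flag
#'
#' The assay repeats each measurement 2--6 times until the replicate SD is
#' within 5 percentage points; software cannot re-run the instrument, so a
#' larger spread is flagged (`qc_pass = FALSE`), never dropped. The SEM is
#' `sqrt(sigma^2 / n)` with the population variance by default.
#'
#' @param percent_levels Numeric vector of replicate percent levels (length
#'   2--6; longer inputs warn and are still used).
#' @param qc_sd_max QC threshold on the replicate SD, percentage points.
#' @param variance `"population"` or `"sample"` variance convention.
#' @return One-row tibble: `mean`, `sd`, `sem`, `n`, `qc_pass`.
#' @examples
#' aggregate_replicates(c(100, 102, 104)) # mean 102, sem ~0.943
#' @export
aggregate_replicates <- function(percent_levels, qc_sd_max = 5,
                                 variance = c("population", "sample")) {
  variance <- match.arg(variance)
  x <- as.numeric(percent_levels)
  n <- length(x)
  if (n < 2) stop_iphplc("insufficient replicates: need at least 2, got %d", n)
  if (n > 6) warning(sprintf("%d replicates exceed the usual 2-6; computing anyway", n))
  if (any(!is.finite(x))) stop_iphplc("replicate percent levels must be finite")
  m <- mean(x)
  var_hat <- if (variance == "population") mean((x - m)^2) else stats::var(x)
  s <- sqrt(var_hat)
  tibble::tibble(
    mean = m,
    sd = s,
    sem = sqrt(var_hat / n),
    n = n,
    qc_pass = s <= qc_sd_max
  )
}

#' Classify a percent change into its band
#'
#' Changes of at most 5, 5--10, 10--20 and more than 20 percent points (in
#' magnitude) are minimal, slight, meaningful and marked respectively.
#' Boundary values fall into the lower band, so |change| = 20 is meaningful
#' and only |change| > 20 is marked.
#'
#' @param delta_pct Signed percent change(s), finite.
#' @param band_edges Ascending band edges (default `c(5, 10, 20)`).
#' @return Factor with levels `minimal`, `slight`, `meaningful`, `marked`.
#' @seealso [change_direction()]
#' @examples
#' classify_change(c(12.6, 0, -25.2)) # meaningful, minimal, marked
#' @export
classify_change <- function(delta_pct, band_edges = c(5, 10, 20)) {
  if (any(!is.finite(delta_pct))) stop_iphplc("percent changes must be finite")
  bands <- c("minimal", "slight", "meaningful", "marked")
  idx <- findInterval(abs(delta_pct), band_edges, left.open = TRUE) + 1L
  factor(bands[idx], levels = bands)
}

#' Direction of a percent change
#'
#' @inheritParams classify_change
#' @return Factor with levels `down`, `none`, `up` (`none` only at exactly 0).
#' @export
change_direction <- function(delta_pct) {
  if (any(!is.finite(delta_pct))) stop_iphplc("percent changes must be finite")
  factor(
    c("down", "none", "up")[sign(delta_pct) + 2],
    levels = c("down", "none", "up")
  )
}

#' Keep antibodies with a high change at any timepoint
#'
#' Retains every row of each antibody whose |change| exceeds the threshold at
#' any analysed timepoint, preserving the input (panel, then timepoint)
#' order. This is the selection behind the "highly up- and down-regulated
#' proteins" dot plots.
#'
#' @param changes Tibble with at least `antibody` and `delta_pct` (typically
#'   the `changes` table of [run_expression_pipeline()]).
#' @param threshold_pct Positive magnitude threshold, percent points
#'   (default 10).
#' @return The filtered tibble.
#' @export
filter_high_changes <- function(changes, threshold_pct = 10) {
  if (!is.numeric(threshold_pct) || threshold_pct <= 0) {
    stop_iphplc("`threshold_pct` must be positive")
  }
  changes <- tibble::as_tibble(changes)
  if (nrow(changes) == 0) return(changes)
  keep <- changes |>
    dplyr::group_by(.data$antibody) |>
    dplyr::summarise(hit = any(abs(.data$delta_pct) > threshold_pct), .groups = "drop")
  changes[changes$antibody %in% keep$antibody[keep$hit], ]
}

#' Run the full expression pipeline on a cohort
#'
#' Quantifies every trace ([quantify_cohort()]), pairs treated and control
#' levels by replicate, applies the housekeeping adjustment per (timepoint,
#' replicate) sample, aggregates replicates, and classifies each antibody's
#' change per timepoint.
#'
#' @inheritParams quantify_cohort
#' @param panel Optional `ip_panel`; when given, antibodies are annotated
#'   with their primary category and results are ordered in panel order.
#' @param config A [pipeline_config()].
#' @return An object of class `ip_result`: a list with
#'   \describe{
#'     \item{changes}{tibble per antibody x timepoint: `antibody`,
#'       `category_label`, `timepoint_h`, `percent_level`, `delta_pct`, `sd`,
#'       `sem`, `n`, `qc_pass`, `band`, `direction`, `clamped_any`}
#'     \item{adjustments}{per (timepoint, replicate): `scale_factor`,
#'       `within_tolerance`}
#'     \item{peak_areas}{the [quantify_cohort()] table}
#'     \item{window, config}{the inputs used}
#'   }
#'   with [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_expression_pipeline <- function(manifest, window, panel = NULL,
                                    config = pipeline_config(),
                                    per_antibody_negative = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  peaks <- quantify_cohort(manifest, window, per_antibody_negative = per_antibody_negative)

  wide <- peaks |>
    dplyr::select(dplyr::all_of(c("antibody", "arm", "timepoint_h", "replicate", "level", "clamped"))) |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("level", "clamped"))
  if (!all(c("level_treated", "level_control") %in% names(wide))) {
    stop_iphplc("cohort must contain both treated and control arms")
  }
  wide$percent_level <- expression_ratio(wide$level_treated, wide$level_control)

  adjusted <- wide |>
    dplyr::group_by(.data$timepoint_h, .data$replicate) |>
    dplyr::group_split() |>
    purrr::map(function(smp) {
      adj <- adjust_housekeeping(
        smp[, c("antibody", "percent_level")],
        housekeeping = config$housekeeping,
        tolerance_pct = config$hk_tolerance_pct
      )
      smp$percent_level <- adj$levels$percent_level
      smp$scale_factor <- adj$report$scale_factor
      smp$hk_within_tolerance <- adj$report$within_tolerance
      smp
    })
  adjustments <- purrr::map(adjusted, function(smp) {
    tibble::tibble(
      timepoint_h = smp$timepoint_h[1],
      replicate = smp$replicate[1],
      scale_factor = smp$scale_factor[1],
      within_tolerance = smp$hk_within_tolerance[1]
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$timepoint_h, .data$replicate)
  adjusted <- purrr::list_rbind(adjusted)

  changes <- adjusted |>
    dplyr::group_by(.data$antibody, .data$timepoint_h) |>
    dplyr::summarise(
      stats = list(aggregate_replicates(
        .data$percent_level,
        qc_sd_max = config$qc_sd_max, variance = config$variance
      )),
      clamped_any = any(.data$clamped_treated | .data$clamped_control),
      .groups = "drop"
    ) |>
    tidyr::unnest("stats") |>
    dplyr::rename(percent_level = "mean") |>
    dplyr::mutate(
      delta_pct = .data$percent_level - 100,
      band = classify_change(.data$delta_pct, config$band_edges),
      direction = change_direction(.data$delta_pct)
    )

  if (!is.null(panel)) {
    stopifnot(inherits(panel, "ip_panel"))
    # a name printed as a primary in two categories keeps its first listing
    primaries <- dplyr::distinct(
      tibble::as_tibble(panel[!panel$is_overlap, c("name", "category")]),
      .data$name,
      .keep_all = TRUE
    )
    changes <- changes |>
      dplyr::left_join(primaries, by = c(antibody = "name")) |>
      dplyr::rename(category_label = "category") |>
      dplyr::mutate(antibody = factor(.data$antibody, levels = unique(primaries$name))) |>
      dplyr::arrange(.data$antibody, .data$timepoint_h) |>
      dplyr::mutate(antibody = as.character(.data$antibody))
  } else {
    changes$category_label <- NA_character_
    changes <- dplyr::arrange(changes, .data$antibody, .data$timepoint_h)
  }
  changes <- changes[, c(
    "antibody", "category_label", "timepoint_h", "percent_level", "delta_pct",
    "sd", "sem", "n", "qc_pass", "band", "direction", "clamped_any"
  )]

  structure(
    list(
      changes = changes,
      adjustments = adjustments,
      peak_areas = peaks,
      window = window,
      config = config
    ),
    class = "ip_result"
  )
}

#' @export
print.ip_result <- function(x, ...) {
  cat(sprintf(
    "<ip_result> %d antibodies x %d timepoint(s); QC pass %.1f%%\n",
    length(unique(x$changes$antibody)),
    length(unique(x$changes$timepoint_h)),
    100 * mean(x$changes$qc_pass)
  ))
  print(x$changes, ...)
  invisible(x)
}

#' Tidy the per-antibody expression changes of a pipeline result
#'
#' @param x An `ip_result`.
#' @param ... Unused.
#' @return The `changes` tibble (one row per antibody x timepoint).
#' @method tidy ip_result
#' @export
tidy.ip_result <- function(x, ...) {
  x$changes
}

#' One-row summary of a pipeline result
#'
#' @param x An `ip_result`.
#' @param ... Unused.
#' @return One-row tibble: antibody/timepoint counts, replicate range, QC
#'   pass rate, per-band counts, clamped count and housekeeping-adjustment
#'   tolerance rate.
#' @method glance ip_result
#' @export
glance.ip_result <- function(x, ...) {
  ch <- x$changes
  band_counts <- table(ch$band)
  tibble::tibble(
    n_antibodies = length(unique(ch$antibody)),
    n_timepoints = length(unique(ch$timepoint_h)),
    n_replicates_min = min(ch$n),
    n_replicates_max = max(ch$n),
    qc_pass_rate = mean(ch$qc_pass),
    n_minimal = as.integer(band_counts[["minimal"]]),
    n_slight = as.integer(band_counts[["slight"]]),
    n_meaningful = as.integer(band_counts[["meaningful"]]),
    n_marked = as.integer(band_counts[["marked"]]),
    n_clamped = sum(ch$clamped_any),
    hk_within_tolerance_rate = mean(x$adjustments$within_tolerance)
  )
}

#' Plot a pipeline result as per-category line graphs
#'
#' @param object An `ip_result`.
#' @param ... Passed to [plot_group_lines()].
#' @return A ggplot.
#' @method autoplot ip_result
#' @export
autoplot.ip_result <- function(object, ...) {
  plot_group_lines(object$changes, ...)
}
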