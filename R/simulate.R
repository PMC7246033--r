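# Synthetic IP-HPLC cohorts with known ground truth.
#
# Each simulated run is a single Gaussian elution peak on a linear baseline
# with additive white detector noise. Ground truth is encoded in the
# quantity the pipeline reports: for a true percent level R, the treated
# NET (specific-binding) area is control_area * (R/100)^2, so the
# subtract-then-sqrt pipeline recovers R exactly in the noise-free limit.
# Every channel additionally captures the same nonspecific-binding area
# (control_area * negative_fraction), which is what the negative-control
# channel measures alone; raw peak areas are therefore net + nonspecific.
#
# Replicate-to-replicate variability has two seeded components:
#   * a shared per-(arm, timepoint, replicate) injection factor
#     (sdlog `replicate_cv`) affecting all antibodies of that sample alike --
#     the component the housekeeping rescale exists to cancel;
#   * an independent per-antibody factor (sdlog `antibody_cv`) that survives
#     the rescale and sets the residual replicate spread.

#' Specify a synthetic IP-HPLC cohort
#'
#' @param antibodies Character vector of target antibody names. The
#'   housekeeping antibodies are appended automatically if absent.
#' @param timepoints_h Subset of `c(12, 24, 48)`.
#' @param truth Ground-truth percent levels: tibble with `antibody`,
#'   `timepoint_h`, `percent` (e.g. 112.6 for a +12.6 % change), or `NULL`
#'   for 100 everywhere. Antibody/timepoint pairs not listed default to 100
#'   (housekeeping proteins are always 100 unless explicitly overridden).
#' @param housekeeping Housekeeping antibody names (default
#'   [housekeeping_antibodies()]).
#' @param control_area_mAU_s Net (specific-binding) control peak area per
#'   antibody, mAU*s.
#' @param center_min,sd_s Gaussian peak centre (minutes) and width (SD,
#'   seconds).
#' @param negative_fraction Nonspecific-binding area as a fraction of the
#'   control net area.
#' @param baseline_slope_mAU_per_min,baseline_intercept_mAU Linear baseline
#'   drift of the detector.
#' @param noise_sd_mAU Additive white detector noise (SD, mAU).
#' @param replicate_cv Log-SD of the shared per-injection factor. The
#'   default 0.042 calibrates the unadjusted percent-level replicate SD to
#'   about 3 points, inside the assay's <= +/-5 working regime.
#' @param antibody_cv Log-SD of the independent per-antibody factor.
#' @param n_replicates Replicates per arm and timepoint (2--6).
#' @param sampling_step_s Detector sampling interval, seconds.
#' @param duration_min Run length, minutes (<= 30).
#' @param seed Integer master seed; fixed seed implies byte-identical output.
#' @return A validated list of class `simulation_spec`.
#' @seealso [simulate_trace()], [simulate_cohort()], [ground_truth()]
#' @export
simulation_spec <- function(antibodies,
                            timepoints_h = c(12, 24, 48),
                            truth = NULL,
                            housekeeping = housekeeping_antibodies(),
                            control_area_mAU_s = 500,
                            center_min = 15,
                            sd_s = 30,
                            negative_fraction = 0.1,
                            baseline_slope_mAU_per_min = 0.05,
                            baseline_intercept_mAU = 1,
                            noise_sd_mAU = 0.02,
                            replicate_cv = 0.042,
                            antibody_cv = 0.008,
                            n_replicates = 4L,
                            sampling_step_s = 1,
                            duration_min = 30,
                            seed = 1L) {
  if (length(antibodies) < 1 || anyDuplicated(antibodies) > 0) {
    stop_iphplc("`antibodies` must be a non-empty set of unique names")
  }
  antibodies <- union(antibodies, housekeeping)
  if (NEG_CONTROL %in% antibodies) {
    stop_iphplc("the reserved label %s cannot be a target antibody", NEG_CONTROL)
  }
  if (!all(timepoints_h %in% c(12, 24, 48)) || length(timepoints_h) < 1) {
    stop_iphplc("`timepoints_h` must be a non-empty subset of {12, 24, 48}")
  }
  if (!is_count(n_replicates) || n_replicates < 2 || n_replicates > 6) {
    stop_iphplc("`n_replicates` must be an integer in [2, 6]")
  }
  for (nm in c(
    "control_area_mAU_s", "center_min", "sd_s", "negative_fraction",
    "sampling_step_s", "duration_min"
  )) {
    v <- get(nm)
    assert_finite_scalar(v, nm)
    if (v <= 0) stop_iphplc("`%s` must be positive", nm)
  }
  for (nm in c("noise_sd_mAU", "replicate_cv", "antibody_cv")) {
    v <- get(nm)
    assert_finite_scalar(v, nm)
    if (v < 0) stop_iphplc("`%s` must be non-negative", nm)
  }
  if (duration_min > 30) stop_iphplc("`duration_min` cannot exceed the 30-minute run")
  if (!is_count(seed) || seed < 0 || seed >= 2^31) {
    stop_iphplc("`seed` must be a non-negative 31-bit integer")
  }

  truth_tbl <- tidyr::expand_grid(antibody = antibodies, timepoint_h = as.numeric(timepoints_h))
  truth_tbl$percent <- 100
  if (!is.null(truth)) {
    truth <- tibble::as_tibble(truth)
    if (!all(c("antibody", "timepoint_h", "percent") %in% names(truth))) {
      stop_iphplc("`truth` needs columns antibody, timepoint_h, percent")
    }
    if (any(!is.finite(truth$percent)) || any(truth$percent <= 0)) {
      stop_iphplc("ground-truth percent levels must be positive")
    }
    unknown <- setdiff(truth$antibody, antibodies)
    if (length(unknown) > 0) {
      stop_iphplc("truth lists unknown antibody: %s", unknown[1])
    }
    key <- paste(truth_tbl$antibody, truth_tbl$timepoint_h)
    hit <- match(key, paste(truth$antibody, truth$timepoint_h))
    truth_tbl$percent[!is.na(hit)] <- truth$percent[hit[!is.na(hit)]]
  }

  structure(
    list(
      antibodies = antibodies,
      housekeeping = housekeeping,
      timepoints_h = as.numeric(timepoints_h),
      truth = truth_tbl,
      control_area_mAU_s = control_area_mAU_s,
      center_min = center_min,
      sd_s = sd_s,
      negative_fraction = negative_fraction,
      baseline_slope_mAU_per_min = baseline_slope_mAU_per_min,
      baseline_intercept_mAU = baseline_intercept_mAU,
      noise_sd_mAU = noise_sd_mAU,
      replicate_cv = replicate_cv,
      antibody_cv = antibody_cv,
      n_replicates = as.integer(n_replicates),
      sampling_step_s = sampling_step_s,
      duration_min = duration_min,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d antibodies x {%s} h x %d replicates; seed %d\n",
    length(x$antibodies), paste(x$timepoints_h, collapse = ", "),
    x$n_replicates, x$seed
  ))
  invisible(x)
}

#' Ground-truth table of a simulation spec
#'
#' @param spec A [simulation_spec()].
#' @return Tibble per (antibody, timepoint): `true_percent`, `true_delta_pct`
#'   and `true_band` (via [classify_change()]).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec$truth |>
    dplyr::rename(true_percent = "percent") |>
    dplyr::mutate(
      true_delta_pct = .data$true_percent - 100,
      true_band = classify_change(.data$true_delta_pct)
    )
}

true_percent_of <- function(spec, antibody, timepoint_h) {
  hit <- spec$truth$antibody == antibody & spec$truth$timepoint_h == timepoint_h
  if (!any(hit)) stop_iphplc("no ground truth for %s at %s h", antibody, timepoint_h)
  spec$truth$percent[hit][1]
}

lognormal_factor <- function(seed, sdlog) {
  if (sdlog == 0) return(1)
  withr::with_seed(seed, exp(rnorm(1, 0, sdlog)))
}

#' Simulate one chromatogram trace
#'
#' The noise-free integral of the simulated peak equals the channel's raw
#' target area (net target + shared nonspecific area); noise components are
#' deterministic functions of the spec seed and the trace identity, so the
#' same (spec, identity) always yields the identical trace.
#'
#' @inheritParams ground_truth
#' @param antibody Antibody name from the spec (ignored for the
#'   negative-control arm, which carries [NEG_CONTROL]).
#' @param arm `"treated"`, `"control"` or `"negative_control"`.
#' @param timepoint_h Timepoint in the spec (`NA` for negative control).
#' @param replicate Replicate index in `1:n_replicates`.
#' @return An [hplc_trace()].
#' @export
simulate_trace <- function(spec, antibody, arm, timepoint_h = NA_real_, replicate = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  arm <- match.arg(arm, ARM_LEVELS)
  if (!is_count(replicate) || replicate < 1 || replicate > spec$n_replicates) {
    stop_iphplc("`replicate` must be in 1..%d", spec$n_replicates)
  }
  nonspecific <- spec$control_area_mAU_s * spec$negative_fraction
  if (arm == "negative_control") {
    antibody <- NEG_CONTROL
    timepoint_h <- NA_real_
    base_area <- nonspecific
  } else {
    if (!antibody %in% spec$antibodies) stop_iphplc("unknown antibody: %s", antibody)
    if (!timepoint_h %in% spec$timepoints_h) {
      stop_iphplc("timepoint %s h is not part of the spec", timepoint_h)
    }
    r <- true_percent_of(spec, antibody, timepoint_h)
    net <- spec$control_area_mAU_s * if (arm == "treated") (r / 100)^2 else 1
    base_area <- net + nonspecific
  }

  s_shared <- lognormal_factor(
    hash_seed(spec$seed, "sample", arm, timepoint_h, replicate),
    spec$replicate_cv
  )
  s_antibody <- lognormal_factor(
    hash_seed(spec$seed, "antibody", antibody, arm, timepoint_h, replicate),
    spec$antibody_cv
  )
  area <- base_area * s_shared * s_antibody

  time_min <- seq(0, spec$duration_min, by = spec$sampling_step_s / 60)
  t_s <- time_min * 60
  amp <- area / (spec$sd_s * sqrt(2 * pi))
  signal <- spec$baseline_intercept_mAU +
    spec$baseline_slope_mAU_per_min * time_min +
    amp * exp(-((t_s - spec$center_min * 60)^2) / (2 * spec$sd_s^2))
  noise <- if (spec$noise_sd_mAU > 0) {
    withr::with_seed(
      hash_seed(spec$seed, "noise", antibody, arm, timepoint_h, replicate),
      rnorm(length(t_s), 0, spec$noise_sd_mAU)
    )
  } else {
    0
  }
  hplc_trace(
    time_min = time_min,
    absorbance_mAU = signal + noise,
    antibody = antibody,
    arm = arm,
    timepoint_h = timepoint_h,
    replicate = replicate
  )
}

#' Default peak window of a simulation spec
#'
#' Centre +/- 5 peak SDs: wide enough that the combination of tail
#' truncation and endpoint baseline subtraction costs well under 0.1 percent
#' of the Gaussian area.
#'
#' @inheritParams ground_truth
#' @return A [peak_window()].
#' @export
spec_window <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  half <- 5 * spec$sd_s / 60
  peak_window(
    max(0, spec$center_min - half),
    min(spec$duration_min, spec$center_min + half)
  )
}

#' Simulate a complete cohort
#'
#' Generates one trace per (antibody, arm, timepoint, replicate) plus one
#' shared negative-control trace per replicate, the manifest, and the
#' ground-truth table. With `dir` set, traces, `manifest.csv` and
#' `ground_truth.csv` are written in the chromatogram file formats;
#' otherwise traces are kept in-memory as a `trace` list-column.
#'
#' @inheritParams ground_truth
#' @param dir Optional output directory.
#' @return List of class `ip_cohort`: `manifest` (tibble, with `trace`
#'   list-column and, if written, `path`), `truth` (see [ground_truth()]),
#'   and `spec`.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  samples <- tidyr::expand_grid(
    antibody = spec$antibodies,
    arm = c("treated", "control"),
    timepoint_h = spec$timepoints_h,
    replicate = seq_len(spec$n_replicates)
  )
  negatives <- tibble::tibble(
    antibody = NEG_CONTROL,
    arm = "negative_control",
    timepoint_h = NA_real_,
    replicate = seq_len(spec$n_replicates)
  )
  manifest <- dplyr::bind_rows(samples, negatives)
  manifest$trace <- purrr::pmap(
    manifest[c("antibody", "arm", "timepoint_h", "replicate")],
    function(antibody, arm, timepoint_h, replicate) {
      simulate_trace(spec, antibody, arm, timepoint_h, replicate)
    }
  )
  manifest$sample_id <- vapply(manifest$trace, function(tr) tr$sample_id, character(1))
  truth <- ground_truth(spec)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, sprintf("trace_%04d.csv", seq_len(nrow(manifest))))
    purrr::walk2(manifest$trace, manifest$path, write_trace)
    mf_out <- manifest[c("path", "sample_id", "antibody", "arm", "timepoint_h", "replicate")]
    mf_out$path <- basename(mf_out$path)
    readr::write_csv(mf_out, file.path(dir, "manifest.csv"), progress = FALSE)
    truth_out <- truth
    truth_out$true_band <- as.character(truth_out$true_band)
    readr::write_csv(truth_out, file.path(dir, "ground_truth.csv"), progress = FALSE)
  }

  structure(list(manifest = manifest, truth = truth, spec = spec), class = "ip_cohort")
}

#' @export
print.ip_cohort <- function(x, ...) {
  cat(sprintf(
    "<ip_cohort> %d traces (%d antibodies x {%s} h x %d replicates + negatives)\n",
    nrow(x$manifest), length(x$spec$antibodies),
    paste(x$spec$timepoints_h, collapse = ", "), x$spec$n_replicates
  ))
  invisible(x)
}

#' Simulate paired cell counts for the proliferation assay
#'
#' Emulates counting the same photographed fields before and after a culture
#' interval: per-field initial counts around `initial_mean`, a per-field
#' growth index of `true_index_pct` plus Gaussian field-to-field dispersion,
#' and integer rounding of the final counts.
#'
#' @param true_index_pct Target mean proliferation index, percent
#'   (> -100).
#' @param n_fields Number of fields (images) counted; default 10.
#' @param dispersion SD of the per-field index around the target, percent
#'   points.
#' @param initial_mean,initial_sd Mean and SD of initial per-field counts.
#' @param arm,duration_h Identity columns carried into the output.
#' @param seed Integer seed; output is deterministic per seed.
#' @return Tibble `arm`, `field_id`, `duration_h`, `initial_count`,
#'   `final_count` suitable for [summarize_proliferation()].
#' @export
simulate_cell_counts <- function(true_index_pct, n_fields = 10, dispersion = 0,
                                 initial_mean = 150, initial_sd = 15,
                                 arm = "treated", duration_h = 24, seed = 1L) {
  assert_finite_scalar(true_index_pct, "true_index_pct")
  if (true_index_pct <= -100) stop_iphplc("`true_index_pct` must exceed -100")
  if (!is_count(n_fields) || n_fields < 1) stop_iphplc("`n_fields` must be a positive integer")
  if (dispersion < 0 || initial_mean <= 0 || initial_sd < 0) {
    stop_iphplc("dispersion and initial-count parameters must be non-negative (mean positive)")
  }
  withr::with_seed(hash_seed(seed, "cellcounts", arm, duration_h), {
    initial <- pmax(1, round(rnorm(n_fields, initial_mean, initial_sd)))
    idx <- true_index_pct + rnorm(n_fields, 0, dispersion)
    final <- pmax(0, round(initial * (1 + idx / 100)))
  })
  tibble::tibble(
    arm = arm,
    field_id = sprintf("field_%02d", seq_len(n_fields)),
    duration_h = duration_h,
    initial_count = as.integer(initial),
    final_count = as.integer(final)
  )
}
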