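# Shared fixture builders. Everything is generated in code; no stored data.

# Small noise-free simulation spec: exact parameter recovery expected.
noise_free_spec <- function(truths_pct, timepoint = 24, n_replicates = 2, seed = 101) {
  antibodies <- sprintf("AB%02d", seq_along(truths_pct))
  simulation_spec(
    antibodies = antibodies,
    timepoints_h = timepoint,
    truth = tibble::tibble(
      antibody = antibodies,
      timepoint_h = timepoint,
      percent = truths_pct
    ),
    noise_sd_mAU = 0, replicate_cv = 0, antibody_cv = 0,
    n_replicates = n_replicates, seed = seed
  )
}

# Flat-topped synthetic trace for integration unit tests.
flat_trace <- function(value = 1, from = 0, to = 3, step = 0.05, ...) {
  t <- seq(from, to, by = step)
  hplc_trace(t, rep(value, length(t)),
    antibody = "AB01", arm = "treated", timepoint_h = 24, replicate = 1, ...
  )
}

# Gaussian peak (amplitude amp mAU, sd in seconds) on an optional linear ramp.
gaussian_trace <- function(amp = 5, center_min = 15, sd_s = 30, step_s = 1,
                           slope = 0, intercept = 0, duration_min = 30) {
  t <- seq(0, duration_min, by = step_s / 60)
  y <- intercept + slope * t + amp * exp(-((t * 60 - center_min * 60)^2) / (2 * sd_s^2))
  hplc_trace(t, y, antibody = "AB01", arm = "treated", timepoint_h = 24, replicate = 1)
}

# Minimal panel catalog for registry tests: 2 categories + housekeeping.
toy_panel <- function() {
  new_panel(tibble::tibble(
    name = c("A", "B", "C", "A", housekeeping_antibodies()),
    category = c("Cat1", "Cat1", "Cat2", "Cat2", rep("Housekeeping", 3)),
    is_overlap = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 3))
  ))
}

# Changes table covering every primary of a panel with fixed deltas.
panel_changes <- function(panel, timepoints = c(12, 24, 48), delta = 0) {
  primaries <- unique(panel$name[!panel$is_overlap])
  tidyr::expand_grid(antibody = primaries, timepoint_h = timepoints) |>
    dplyr::mutate(delta_pct = delta, percent_level = 100 + delta)
}
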