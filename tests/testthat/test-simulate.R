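test_that("noise-free simulated peaks integrate to their target areas", {
  spec <- noise_free_spec(c(120, 80))
  win <- spec_window(spec)
  nonspecific <- spec$control_area_mAU_s * spec$negative_fraction

  ctrl <- correct_baseline(simulate_trace(spec, "AB01", "control", 24, 1), win)
  expect_equal(
    integrate_window(ctrl, win),
    spec$control_area_mAU_s + nonspecific,
    tolerance = 1e-3
  )
  trt <- correct_baseline(simulate_trace(spec, "AB01", "treated", 24, 1), win)
  expect_equal(
    integrate_window(trt, win),
    spec$control_area_mAU_s * 1.2^2 + nonspecific,
    tolerance = 1e-3
  )
  neg <- correct_baseline(simulate_trace(spec, "AB01", "negative_control"), win)
  expect_equal(integrate_window(neg, win), nonspecific, tolerance = 1e-3)

  # truth 100%: treated and control areas agree within 0.1 %
  ctrl2 <- correct_baseline(simulate_trace(spec, "AB02", "control", 24, 1), win)
  trt80 <- correct_baseline(simulate_trace(spec, "AB02", "treated", 24, 1), win)
  expect_equal(
    integrate_window(trt80, win) - nonspecific,
    (integrate_window(ctrl2, win) - nonspecific) * 0.8^2,
    tolerance = 1e-3
  )
})

test_that("simulation is deterministic per seed and identity", {
  spec <- simulation_spec(
    antibodies = c("X1", "X2"), timepoints_h = c(12, 24),
    n_replicates = 2, seed = 77
  )
  a <- simulate_trace(spec, "X1", "treated", 12, 1)
  b <- simulate_trace(spec, "X1", "treated", 12, 1)
  expect_identical(a$data, b$data)

  other <- simulate_trace(spec, "X1", "treated", 12, 2)
  expect_false(identical(a$data$absorbance_mAU, other$data$absorbance_mAU))

  # byte-identical files from two cohort realisations of the same spec
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(spec, dir = d1)
  simulate_cohort(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f)),
      info = f
    )
  }
})

test_that("cohort manifests count out antibodies, arms and replicates", {
  spec <- simulation_spec(
    antibodies = sprintf("T%02d", 1:7), timepoints_h = c(12, 24, 48),
    n_replicates = 3, seed = 5
  )
  cohort <- simulate_cohort(spec)
  # 7 targets + 3 housekeeping, 2 arms, 3 timepoints, 3 replicates + 3 negatives
  expect_equal(nrow(cohort$manifest), 10 * 2 * 3 * 3 + 3)
  expect_equal(sum(cohort$manifest$arm == "negative_control"), 3L)
  expect_true(all(
    cohort$manifest$antibody[cohort$manifest$arm == "negative_control"] == NEG_CONTROL
  ))
  expect_equal(nrow(cohort$truth), 10 * 3)
})

test_that("written cohorts round-trip through the file formats", {
  spec <- noise_free_spec(c(115), n_replicates = 2)
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(spec, dir = dir)
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), nrow(cohort$manifest))

  result <- run_expression_pipeline(mf, spec_window(spec))
  truth <- cohort$truth
  joined <- dplyr::inner_join(tidy(result), truth, by = c("antibody", "timepoint_h"))
  # file round trip costs at most the 1e-6 relative formatting error
  expect_equal(joined$percent_level, joined$true_percent, tolerance = 1e-4)
})

test_that("ground-truth table is consistent with the band classifier", {
  spec <- noise_free_spec(c(95.5, 104, 111, 79.9))
  truth <- ground_truth(spec)
  expect_equal(truth$true_delta_pct, truth$true_percent - 100)
  expect_equal(
    as.character(truth$true_band),
    as.character(classify_change(truth$true_delta_pct))
  )
})

test_that("simulated cell counts hit the target index up to rounding", {
  counts <- simulate_cell_counts(73.1, n_fields = 10, dispersion = 0, seed = 3)
  idx <- proliferation_index(counts$initial_count, counts$final_count)
  expect_true(all(abs(idx - 73.1) <= 100 * 0.5 / min(counts$initial_count)))

  treated <- summarize_proliferation(
    simulate_cell_counts(73.1, dispersion = 0, arm = "treated", seed = 9)
  )
  control <- summarize_proliferation(
    simulate_cell_counts(69.9, dispersion = 0, arm = "control", seed = 9)
  )
  expect_equal(index_difference(treated, control), 3.2, tolerance = 0.5)

  expect_identical(
    simulate_cell_counts(50, seed = 4)$final_count,
    simulate_cell_counts(50, seed = 4)$final_count
  )
  expect_error(simulate_cell_counts(50, n_fields = 0), "positive integer")
  expect_error(simulate_cell_counts(-100), "exceed -100")
})

test_that("simulation specs validate their parameters", {
  expect_error(simulation_spec(character(0)), "non-empty")
  expect_error(simulation_spec("A", timepoints_h = 36), "subset")
  expect_error(simulation_spec("A", n_replicates = 1), "\\[2, 6\\]")
  expect_error(simulation_spec("A", n_replicates = 7), "\\[2, 6\\]")
  expect_error(simulation_spec("A", control_area_mAU_s = -5), "positive")
  expect_error(
    simulation_spec("A", truth = tibble::tibble(
      antibody = "A", timepoint_h = 24, percent = -10
    )),
    "positive"
  )
  expect_error(
    simulation_spec("A", truth = tibble::tibble(
      antibody = "ZZZ", timepoint_h = 24, percent = 110
    )),
    "unknown antibody"
  )
  expect_error(simulate_trace(noise_free_spec(110), "AB01", "treated", 36, 1), "not part")
})
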