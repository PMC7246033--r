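test_that("group series cover primaries plus resolved overlaps in panel order", {
  panel <- load_panel()
  changes <- panel_changes(panel, delta = 7.5)

  ras <- build_group_series(changes, panel, "RAS signaling")
  expect_equal(nrow(ras), 22L)
  expect_false(any(ras$is_overlap))

  nfkb <- build_group_series(changes, panel, "NFkB signaling")
  expect_equal(nrow(nfkb), 18L) # 12 primaries + 6 resolved overlaps
  expect_equal(sum(nfkb$is_overlap), 6L)
  # overlap series take the primary's measured values
  expect_equal(nfkb$t24, rep(7.5, 18))
  # identical fixed order to the panel listing
  expect_equal(nfkb$antibody, panel$name[panel$category == "NFkB signaling"])

  # empty change list: series of all-missing values, not an error
  empty <- build_group_series(changes[0, ], panel, "RAS signaling")
  expect_equal(nrow(empty), 22L)
  expect_true(all(is.na(empty$t12)) && all(is.na(empty$t24)) && all(is.na(empty$t48)))

  expect_error(build_group_series(changes, panel, "No such pathway"), "unknown")
})

test_that("series and dot builders never modify the change values", {
  panel <- toy_panel()
  changes <- panel_changes(panel, delta = 12)
  before <- changes
  invisible(build_group_series(changes, panel, "Cat1"))
  invisible(build_dot_plot_data(changes, panel))
  expect_identical(changes, before)
  # referential integrity: every series antibody exists in the catalog
  series <- build_group_series(changes, panel, "Cat2")
  expect_true(all(series$antibody %in% panel$name))
})

test_that("dot-plot data applies the high-change threshold and sign split", {
  changes <- tibble::tibble(
    antibody = c("A", "B", "C"),
    timepoint_h = 24,
    delta_pct = c(12.6, 4.0, -15)
  )
  dots <- build_dot_plot_data(changes, threshold_pct = 10)
  expect_equal(dots$antibody, c("A", "C"))
  expect_equal(as.character(dots$direction), c("up", "down"))
  expect_equal(nrow(build_dot_plot_data(changes[changes$delta_pct == 0, ])), 0L)

  # threshold 20 excludes a known fraction with |delta| = 15
  withr::with_seed(21, {
    n <- 40
    deltas <- c(rep(15, 12), runif(n - 12, -5, 5))
  })
  cohort_changes <- tibble::tibble(
    antibody = sprintf("P%02d", 1:n), timepoint_h = 24, delta_pct = deltas
  )
  expect_equal(nrow(build_dot_plot_data(cohort_changes, threshold_pct = 20)), 0L)
  expect_equal(nrow(build_dot_plot_data(cohort_changes, threshold_pct = 10)), 12L)
})

test_that("exports are deterministic CSVs with the documented columns", {
  spec <- noise_free_spec(c(118, 88, 104))
  cohort <- simulate_cohort(spec)
  result <- run_expression_pipeline(cohort$manifest, spec_window(spec))

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  files1 <- export_results(result, dir1, figures = FALSE)
  files2 <- export_results(result, dir2, figures = FALSE)

  res <- readr::read_csv(files1[["results"]], show_col_types = FALSE)
  expect_equal(nrow(res), nrow(result$changes)) # one row per antibody x timepoint
  expect_true(all(c(
    "antibody", "category_label", "timepoint_h", "percent_level", "delta_pct",
    "sem", "n", "qc_pass", "band", "direction", "clamped_any"
  ) %in% names(res)))

  for (f in names(files1)) {
    expect_identical(
      readBin(files1[[f]], "raw", file.size(files1[[f]])),
      readBin(files2[[f]], "raw", file.size(files2[[f]])),
      info = f
    )
  }

  # empty cohort: headers-only CSVs
  empty_result <- result
  empty_result$changes <- result$changes[0, ]
  dir3 <- withr::local_tempdir()
  files3 <- export_results(empty_result, dir3, figures = FALSE)
  expect_equal(nrow(readr::read_csv(files3[["results"]], show_col_types = FALSE)), 0L)
})

test_that("plot builders return ggplot objects", {
  panel <- load_panel()
  changes <- panel_changes(panel, delta = 11)
  expect_s3_class(plot_group_lines(changes), "ggplot")
  expect_s3_class(plot_star(changes, panel, "RAS signaling"), "ggplot")
  expect_s3_class(plot_dot_changes(build_dot_plot_data(changes, panel)), "ggplot")
})
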