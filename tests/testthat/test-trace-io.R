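test_that("trace files round-trip identity and series", {
  t <- seq(0, 30, by = 1 / 60) # 1801 points, 1-s sampling
  set.seed(42)
  tr <- hplc_trace(t, 2 + 0.1 * t + rnorm(length(t), 0, 0.05),
    antibody = "Ki-67", arm = "treated", timepoint_h = 24, replicate = 3,
    sample_id = "run-007"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)

  expect_equal(nrow(back$data), 1801L)
  expect_identical(back$sample_id, "run-007")
  expect_identical(back$antibody, "Ki-67")
  expect_identical(back$arm, "treated")
  expect_identical(back$timepoint_h, 24)
  expect_identical(back$replicate, 3L)
  expect_equal(back$wavelength_nm, 280)
  expect_equal(back$flow_mL_min, 0.4)
  expect_equal(back$data$time_min, tr$data$time_min, tolerance = 1e-6)
  expect_equal(back$data$absorbance_mAU, tr$data$absorbance_mAU, tolerance = 1e-6)
})

test_that("negative-control traces carry the reserved label and no timepoint", {
  tr <- hplc_trace(0:10, rep(1, 11), antibody = NEG_CONTROL, arm = "negative_control")
  path <- withr::local_tempfile()
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$antibody, NEG_CONTROL)
  expect_true(is.na(back$timepoint_h))
})

test_that("invalid traces and trace files are rejected", {
  expect_error(
    hplc_trace(c(0, 2, 1), c(1, 1, 1), "A", "treated", 24),
    "strictly increasing"
  )
  expect_error(
    hplc_trace(c(0, 1), c(1, 1, 1), "A", "treated", 24),
    "lengths differ"
  )
  expect_error(
    hplc_trace(c(0, 40), c(1, 1), "A", "treated", 24),
    "30-minute"
  )
  expect_error(
    hplc_trace(c(0, 1), c(1, NaN), "A", "treated", 24),
    "finite"
  )
  expect_error(hplc_trace(numeric(0), numeric(0), "A", "treated"), "at least 2")

  path <- withr::local_tempfile()
  writeLines(
    c("# antibody: A", "# arm: treated", "time_min,absorbance_mAU",
      "0,1", "2,1", "1,1"),
    path
  )
  expect_error(read_trace(path), "strictly increasing")

  writeLines(c("0,1", "1,2"), path)
  expect_error(read_trace(path), "missing identity")
})

test_that("reader ignores extra comments and is locale-independent", {
  path <- withr::local_tempfile()
  writeLines(
    c(
      "# exported by instrument X", "# antibody: B7", "# arm: control",
      "# timepoint_h: 12", "# replicate: 2",
      "time_min,absorbance_mAU",
      "0.5,1.25", "# stray mid-file comment", "1.5,2.75", "2.5,0.125"
    ),
    path
  )
  tr <- read_trace(path)
  expect_equal(tr$data$time_min, c(0.5, 1.5, 2.5))
  expect_equal(tr$data$absorbance_mAU, c(1.25, 2.75, 0.125))
  expect_identical(tr$replicate, 2L)
})

test_that("manifests resolve relative paths and validate arms", {
  dir <- withr::local_tempdir()
  tr <- flat_trace()
  write_trace(tr, file.path(dir, "t1.csv"))
  readr::write_csv(
    tibble::tibble(
      path = "t1.csv", sample_id = "s", antibody = "AB01",
      arm = "treated", timepoint_h = 24, replicate = 1L
    ),
    file.path(dir, "manifest.csv")
  )
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_true(file.exists(mf$path[1]))

  readr::write_csv(
    tibble::tibble(
      path = "t1.csv", sample_id = "s", antibody = "AB01",
      arm = "exposed", timepoint_h = 24, replicate = 1L
    ),
    file.path(dir, "bad.csv")
  )
  expect_error(read_manifest(file.path(dir, "bad.csv")), "unknown arm")
})
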