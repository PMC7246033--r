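test_that("linear baselines are removed exactly inside the window", {
  win <- peak_window(5, 25)

  flat <- gaussian_trace(amp = 0, intercept = 5)
  corrected <- correct_baseline(flat, win)
  inside <- corrected$data$time_min >= 5 & corrected$data$time_min <= 25
  expect_equal(corrected$data$absorbance_mAU[inside], rep(0, sum(inside)))
  expect_equal(corrected$data$absorbance_mAU[!inside], flat$data$absorbance_mAU[!inside])

  ramp <- gaussian_trace(amp = 0, intercept = 2, slope = 0.3)
  corrected <- correct_baseline(ramp, win)
  expect_equal(corrected$data$absorbance_mAU[inside], rep(0, sum(inside)),
    tolerance = 1e-12
  )

  # Gaussian peak on a ramp: correction recovers the pure Gaussian at
  # interior points (the peak's own tails at the endpoints are ~exp(-50))
  peak_on_ramp <- gaussian_trace(amp = 8, intercept = 2, slope = 0.3)
  pure <- gaussian_trace(amp = 8)
  corrected <- correct_baseline(peak_on_ramp, win)
  expect_equal(
    corrected$data$absorbance_mAU[inside],
    pure$data$absorbance_mAU[inside],
    tolerance = 1e-9
  )

  expect_error(correct_baseline(flat, peak_window(5, 31)), "outside the trace")
})

test_that("window integration is a trapezoid in mAU*s", {
  # constant 1 mAU for 1 min -> 60 mAU*s
  expect_equal(integrate_window(flat_trace(1), peak_window(1, 2)), 60)
  # all-zero trace -> 0
  expect_equal(integrate_window(flat_trace(0), peak_window(0, 3)), 0)
  expect_error(
    integrate_window(flat_trace(1, step = 1), peak_window(1.2, 1.8)),
    "fewer than 2"
  )
})

test_that("Gaussian peak area matches closed form and quadrature oracle", {
  amp <- 5
  sd_s <- 30
  tr <- gaussian_trace(amp = amp, sd_s = sd_s, step_s = 1)
  win <- peak_window(15 - 4 * sd_s / 60, 15 + 4 * sd_s / 60)
  area <- integrate_window(tr, win)

  expect_equal(area, amp * sd_s * sqrt(2 * pi), tolerance = 1e-3)

  oracle <- stats::integrate(
    function(t_s) amp * exp(-((t_s - 900)^2) / (2 * sd_s^2)),
    lower = 900 - 4 * sd_s, upper = 900 + 4 * sd_s,
    rel.tol = 1e-12
  )$value
  expect_equal(area, oracle, tolerance = 1e-3)

  # convergence: halving the sampling step moves the area by < 0.05 %
  half <- integrate_window(gaussian_trace(amp = amp, sd_s = sd_s, step_s = 0.5), win)
  expect_lt(abs(half - area) / area, 5e-4)
})

test_that("areas and levels are scale-equivariant", {
  win <- peak_window(13, 17)
  base <- gaussian_trace(amp = 5)
  base_area <- integrate_window(base, win)
  for (c_mult in c(0.25, 4, 100)) {
    scaled <- base
    scaled$data$absorbance_mAU <- scaled$data$absorbance_mAU * c_mult
    area <- integrate_window(scaled, win)
    expect_equal(area, base_area * c_mult, tolerance = 1e-12)
    expect_equal(
      expression_level(area),
      expression_level(base_area) * sqrt(c_mult),
      tolerance = 1e-12
    )
  }
})

test_that("negative-control subtraction clamps and flags", {
  expect_equal(
    net_peak_area(500, 100),
    tibble::tibble(net_area_mAU_s = 400, clamped = FALSE)
  )
  expect_equal(
    net_peak_area(100, 100),
    tibble::tibble(net_area_mAU_s = 0, clamped = FALSE)
  )
  expect_equal(
    net_peak_area(80, 100),
    tibble::tibble(net_area_mAU_s = 0, clamped = TRUE)
  )
  expect_error(net_peak_area(-1, 0), "non-negative")
  expect_error(net_peak_area(1, -5), "non-negative")
})

test_that("net area is monotone in both arguments", {
  raws <- seq(0, 200, by = 25)
  nets_up <- net_peak_area(raws, 50)$net_area_mAU_s
  expect_true(all(diff(nets_up) >= 0))
  negs <- seq(0, 200, by = 25)
  nets_down <- net_peak_area(120, negs)$net_area_mAU_s
  expect_true(all(diff(nets_down) <= 0))
})

test_that("expression level is the square root of net area", {
  expect_equal(expression_level(400), 20)
  expect_equal(expression_level(0), 0)
  expect_equal(expression_level(2), sqrt(2), tolerance = 1e-9)
  expect_error(expression_level(-0.1), "non-negative")

  # sqrt compresses ratios: level ratio equals sqrt of area ratio
  withr::with_seed(11, {
    a <- stats::runif(20, 1, 1000)
    b <- stats::runif(20, 1, 1000)
  })
  expect_equal(
    expression_level(a) / expression_level(b),
    sqrt(a / b),
    tolerance = 1e-12
  )
})
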