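ratio_curve_series <- function(probe = default_probe(), rr = 0.5,
                               grid = seq(3.5, 7.4, 0.1)) {
  titration_series(grid, sigmoid_value(probe, grid) / rr, assay = "ratio")
}

test_that("full calibration is a fixed point on noiseless ratio data", {
  cal <- build_calibration_full(ratio_curve_series())
  p <- default_probe()
  expect_equal(cal$pka, p$pka, tolerance = 1e-6)
  expect_equal(cal$slope, p$slope, tolerance = 1e-6)
  expect_equal(cal$bottom, p$bottom / 0.5, tolerance = 1e-6)
  expect_equal(cal$top, p$top / 0.5, tolerance = 1e-6)
  expect_identical(cal$mode, "full")
  expect_error(build_calibration_full(
    titration_series(4:8, rep(1, 5), assay = "ratio")), "constant")
})

test_that("full calibration recovers pKa from noisy fixed-cell ratios", {
  # 2 wells x 3 fields per pH, 3% CV
  grid <- seq(4, 6, 0.5)
  errs <- vapply(1:20, function(s) {
    noisy <- withr::with_seed(s, {
      ph <- rep(grid, each = 6)
      r <- sigmoid_value(default_probe(), ph) / 0.5
      titration_series(ph[order(ph)], (r * (1 + rnorm(length(r), 0, 0.03))),
                       assay = "ratio")
    })
    abs(build_calibration_full(noisy)$pka - 5.4)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("anchored calibration passes through its anchor and scales
          equivariantly", {
  sol <- fit_sigmoid(ratio_curve_series())
  r5 <- sigmoid_value(sol, 5.0)
  # anchor equal to the solution ratio reproduces the solution curve
  cal1 <- build_calibration_anchored(r5, 5.0, sol)
  expect_equal(sigmoid_value(cal1, 5.0), r5, tolerance = 1e-9)
  expect_equal(cal1$pka, sol$pka, tolerance = 1e-6)
  expect_equal(cal1$bottom, sol$bottom, tolerance = 1e-4)
  # doubling the anchor doubles the plateaus, pKa and slope unchanged
  cal2 <- build_calibration_anchored(2 * r5, 5.0, sol)
  expect_equal(abs(sigmoid_value(cal2, 5.0) / (2 * r5) - 1), 0,
               tolerance = 1e-9)
  expect_equal(cal2$pka, cal1$pka, tolerance = 1e-6)
  expect_equal(cal2$slope, cal1$slope, tolerance = 1e-6)
  expect_equal(cal2$bottom, 2 * cal1$bottom, tolerance = 1e-4)
  expect_equal(cal2$top, 2 * cal1$top, tolerance = 1e-4)
  # k-scaled measurements interpolate to identical pH
  r <- sigmoid_value(cal1, c(4.4, 5.1, 5.9))
  expect_equal(interpolate_ph(2 * r, cal2)$ph, interpolate_ph(r, cal1)$ph,
               tolerance = 1e-6)
  expect_error(build_calibration_anchored(-1, 5.0, sol), "positive")
  expect_error(build_calibration_anchored(1, 9.5, ratio_curve_series()),
               "outside")
})

test_that("interpolation inverts the calibration sigmoid on the valid
          range", {
  cal <- build_calibration_full(ratio_curve_series())
  expect_equal(interpolate_ph((cal$bottom + cal$top) / 2, cal)$ph, cal$pka,
               tolerance = 1e-9)
  for (p in seq(4.5, 6.3, 0.1)) {
    r <- sigmoid_value(cal, p)
    expect_equal(interpolate_ph(r, cal)$ph, p, tolerance = 1e-9)
  }
  # monotone: increasing ratio means decreasing pH for an acid-bright curve
  rr <- seq(cal$bottom + 0.05 * (cal$top - cal$bottom),
            cal$top - 0.05 * (cal$top - cal$bottom), length.out = 25)
  expect_true(all(diff(interpolate_ph(rr, cal)$ph) < 0))
})

test_that("near-asymptote ratios are flagged with a side, extreme pH flagged
          extrapolated", {
  cal <- build_calibration_full(ratio_curve_series())
  span <- cal$top - cal$bottom
  expect_identical(interpolate_ph(cal$top - 0.001 * span, cal)$flag,
                   "above_range")
  expect_identical(interpolate_ph(cal$bottom + 0.001 * span, cal)$flag,
                   "below_range")
  expect_identical(interpolate_ph(cal$top + 1, cal)$flag, "above_range")
  expect_true(is.na(interpolate_ph(cal$top + 1, cal)$ph))
  # a curve fitted on a narrow pH window flags out-of-window results
  narrow <- build_calibration_full(ratio_curve_series(grid = seq(4.6, 6.0,
                                                                 0.2)))
  expect_identical(interpolate_ph(sigmoid_value(narrow, 6.2),
                                  narrow)$flag, "extrapolated")
})

test_that("calibration JSON round-trips", {
  cal <- build_calibration_anchored(1.7, 5.0, fit_sigmoid(ratio_curve_series()))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  cal2 <- read_calibration(f)
  expect_equal(cal2$bottom, cal$bottom)
  expect_equal(cal2$top, cal$top)
  expect_equal(cal2$pka, cal$pka)
  expect_equal(cal2$slope, cal$slope)
  expect_identical(cal2$mode, "anchored")
  expect_equal(cal2$anchor$ratio, 1.7)
  r <- seq(0.2, 1.8, 0.2)
  expect_equal(interpolate_ph(r, cal2), interpolate_ph(r, cal))
})
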