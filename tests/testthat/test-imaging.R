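make_test_stack <- function(dep, indep, pixel_size = 0.2, z_spacing = 0.75,
                            corrected = TRUE) {
  st <- image_stack(list(ph_dependent = dep, ph_independent = indep),
                    pixel_size = pixel_size, z_spacing = z_spacing)
  st$meta$background_corrected <- corrected
  st
}

test_that("background correction subtracts the per-plane 5th percentile and
          is idempotent afterwards", {
  a <- array(100, dim = c(2, 10, 10))
  st <- make_test_stack(a, a, corrected = FALSE)
  bc <- background_correct(st)
  expect_true(all(bc$channels$ph_independent == 0))
  expect_equal(unname(bc$meta$background_subtracted["ph_independent", ]),
               c(100, 100))
  # sparse bright puncta on a zero background are untouched
  b <- array(0, dim = c(1, 20, 20))
  b[1, 10, 10] <- 500
  st2 <- background_correct(make_test_stack(b, b, corrected = FALSE))
  expect_equal(max(st2$channels$ph_dependent), 500)
  expect_equal(sum(st2$channels$ph_dependent), 500)
  # idempotence once the 5th percentile is zero
  st3 <- background_correct(st2)
  expect_identical(st3$channels, st2$channels)
})

test_that("background correction removes a flat background exactly and most
          of a gradient background", {
  mk <- function(bg, grad) sim_config(
    shape = c(5, 64, 64), n_organelles = 1, ph = c(5.0, 0),
    background = bg, background_gradient = grad,
    read_noise_sd = 0, photon_scale = 0, seed = 6)
  truth <- simulate_stack(mk(0, 0))$truth
  clean <- simulate_stack(mk(0, 0), truth = truth)$stack
  flat <- background_correct(simulate_stack(mk(50, 0), truth = truth)$stack)
  # a constant background is the plane's 5th percentile: removed exactly
  expect_equal(flat$channels$ph_independent,
               clean$channels$ph_independent, tolerance = 1e-9)
  # a linear ramp (45..55 a.u.) is only partially removable by a single
  # per-plane scalar; the subtracted value sits at the ramp's low tail
  grad <- background_correct(simulate_stack(mk(50, 5), truth = truth)$stack)
  q <- grad$meta$background_subtracted["ph_independent", ]
  expect_true(all(q >= 45 & q <= 47))
})

test_that("sum projection conserves intensity and widens precision", {
  a <- array(60000, dim = c(4, 8, 8))   # would overflow 16-bit
  st <- make_test_stack(a, a)
  proj <- sum_project(st)
  expect_true(all(proj$ph_dependent == 240000))
  expect_equal(sum(proj$ph_dependent), sum(a))
  # single plane is the identity
  one <- array(7, dim = c(1, 4, 4))
  expect_equal(sum_project(make_test_stack(one, one))$ph_dependent[1, 1], 7)
  expect_warning(sum_project(make_test_stack(one, one, corrected = FALSE)),
                 "background")
})

test_that("otsu masking isolates puncta on a two-level image", {
  img <- matrix(10, 24, 24)
  puncta <- cbind(c(5, 6, 12, 18), c(5, 6, 15, 20))
  img[puncta] <- 1000
  msk <- make_mask(img)
  expect_identical(which(msk), which(img == 1000))
  expect_true(attr(msk, "threshold") > 10 && attr(msk, "threshold") <= 1000)
  # fixed threshold of 0 keeps every positive pixel
  expect_true(all(make_mask(img, "fixed", 0)))
  # threshold above the maximum gives an empty mask with a warning
  expect_warning(m0 <- make_mask(img, "fixed", 2000), "empty")
  expect_false(any(m0))
})

test_that("field ratio reproduces proportional channels and flags empty
          masks", {
  indep <- array(rep(100, 2 * 12 * 12), dim = c(2, 12, 12))
  dep <- indep * 0.5
  st <- make_test_stack(dep, indep)
  fr <- field_ratio(st, mask = matrix(TRUE, 12, 12))
  expect_equal(fr$ratio, 0.5)
  # scale invariance: common gain leaves the ratio unchanged
  st2 <- make_test_stack(dep * 37, indep * 37)
  expect_equal(field_ratio(st2, mask = matrix(TRUE, 12, 12))$ratio, 0.5)
  # empty mask is flagged data, not an error
  fr0 <- field_ratio(st, mask = matrix(FALSE, 12, 12))
  expect_identical(fr0$flag, "empty_mask")
  expect_true(is.na(fr0$ratio))
})

test_that("noiseless single-pH field ratio equals the generative sigmoid
          ratio exactly", {
  cfg <- sim_config(shape = c(5, 48, 48), n_organelles = 5, ph = c(4.8, 0),
                    background = 0, background_gradient = 0,
                    read_noise_sd = 0, photon_scale = 0, seed = 13)
  sim <- simulate_stack(cfg)
  st <- sim$stack
  st$meta$background_corrected <- TRUE   # zero background, nothing to remove
  fr <- field_ratio(st, mask = matrix(TRUE, 48, 48))
  expect_equal(fr$ratio,
               sigmoid_value(cfg$probe, 4.8) / cfg$reference_response,
               tolerance = 1e-12)
})

test_that("object ratios integrate both channels per object and propagate
          calibration flags", {
  plane <- matrix(0, 20, 20)
  plane[4:6, 4:6] <- 1000
  plane[14:17, 12:15] <- 800
  dep <- plane * 1.3
  recs <- segment_objects(plane, mask = plane > 0, units = "pixel",
                          area_filter = c(1, 1500))
  expect_identical(nrow(recs), 2L)
  out <- object_ratios(recs, dep, plane)
  expect_equal(out$ratio, c(1.3, 1.3))
  expect_equal(out$intensity_indep, c(9 * 1000, 16 * 800))
  # a ratio beyond the calibration asymptote is flagged, not interpolated
  cal <- build_calibration_full(titration_series(
    seq(3.5, 7.4, 0.1), sigmoid_value(default_probe(), seq(3.5, 7.4, 0.1)) / 0.5,
    assay = "ratio"))
  out2 <- object_ratios(recs, dep * 10, plane, cal)
  expect_true(all(out2$flag == "above_range"))
  expect_true(all(is.na(out2$ph)))
})

test_that("ratio images map masked ratios onto the blue-green-red LUT in
          order", {
  # uniform ratio at the display minimum -> first LUT entry (pure blue)
  indep <- matrix(1000, 16, 16)
  dep <- indep * 0.5
  img <- ratio_image(list(ph_dependent = dep, ph_independent = indep),
                     min_ratio = 0.5, max_ratio = 2.5,
                     mask = matrix(TRUE, 16, 16))
  idx <- attr(img, "lut_index")
  expect_true(all(idx == 1))
  expect_equal(img[1, 1, ], c(0, 0, 1))
  # midway ratio lands mid-LUT (green region)
  img2 <- ratio_image(list(ph_dependent = indep * 1.5,
                           ph_independent = indep),
                      min_ratio = 0.5, max_ratio = 2.5,
                      mask = matrix(TRUE, 16, 16))
  expect_true(all(attr(img2, "lut_index") %in% 128:129))
  expect_equal(img2[8, 8, ], c(0, 1, 0), tolerance = 0.01)
  # two organelles at pH 4.6 and 6.0 occupy ordered, distinct LUT bins
  cfg <- sim_config(shape = c(3, 48, 48), n_organelles = 0, background = 0,
                    background_gradient = 0, read_noise_sd = 0,
                    photon_scale = 0, seed = 3)
  tr <- data.frame(id = 1:2, z = 1, y = c(14, 34), x = c(14, 34),
                   radius_um = 0.6, ph = c(4.6, 6.0), load = 2e4)
  sim <- simulate_stack(cfg, truth = tr)
  st <- sim$stack; st$meta$background_corrected <- TRUE
  rim <- ratio_image(st, min_ratio = 0.3, max_ratio = 2.2)
  li <- attr(rim, "lut_index")
  acid_bin <- li[15, 15]; mild_bin <- li[35, 35]
  expect_gt(acid_bin, mild_bin)   # more acidic = higher ratio = redder bin
  expect_gt(mild_bin, 0)
})

test_that("photobleach curves normalize to the first cycle and round-trip
          simulated fractions", {
  pc <- photobleach_curve(c(500, 500, 500))
  expect_equal(pc$f_over_f0, c(1, 1, 1))
  expect_equal(attr(pc, "fraction_lost"), 0)
  for (f in c(0.12, 0.83)) {
    s <- simulate_photobleach(2000, f, 50, noise_cv = 0, seed = 2)
    pc <- photobleach_curve(s)
    expect_equal(pc$f_over_f0[1], 1)
    expect_equal(attr(pc, "fraction_lost"), f, tolerance = 1e-12)
  }
  expect_error(photobleach_curve(c(5)), "cycles")
})

test_that("nuclei counting respects width filters and local contrast", {
  expect_identical(as.integer(count_nuclei(matrix(10, 64, 64),
                                           pixel_size = 0.5)), 0L)
  # 7 well-separated 10-um nuclei at 150 gray levels over background
  img <- matrix(20, 200, 200)
  centers <- expand.grid(r = c(40, 100, 160), c = c(40, 100, 160))[1:7, ]
  for (i in 1:7) {
    rr <- outer((1:200 - centers$r[i])^2, (1:200 - centers$c[i])^2, "+")
    img[rr <= 10^2] <- 170    # radius 10 px = 5 um -> diameter 10 um
  }
  expect_identical(as.integer(count_nuclei(img, pixel_size = 0.5)), 7L)
  # a 2-um speck is below the 5-um minimum width
  img2 <- matrix(20, 64, 64)
  img2[30:31, 30:31] <- 200
  expect_identical(as.integer(count_nuclei(img2, pixel_size = 0.5)), 0L)
})
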