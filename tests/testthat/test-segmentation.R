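# The splitting rule: two touching puncta are separate objects when the
# saddle between their peaks is <= 50% of the lower peak. Checked against
# brute-force BFS + threshold-sweep oracles on small synthetic planes.

test_that("hand-built profiles split exactly at the saddle rule boundary", {
  seg_count <- function(vals) {
    plane <- matrix(vals, nrow = 1)
    recs <- segment_objects(plane, mask = matrix(TRUE, 1, length(vals)),
                            units = "pixel", area_filter = c(0, Inf),
                            radius_filter = c(0, Inf))
    nrow(recs)
  }
  # saddle 30 is 37.5% of the lower peak 80 -> split
  expect_identical(seg_count(c(100, 30, 80)), 2L)
  # saddle 70 is 87.5% of the lower peak 80 -> one object
  expect_identical(seg_count(c(100, 70, 80)), 1L)
  # saddle exactly 50% of the lower peak -> split (rule is <=)
  expect_identical(seg_count(c(100, 40, 80)), 2L)
  # two separated components are always two objects
  plane <- matrix(c(9, 0, 0, 0, 9), nrow = 1)
  recs <- segment_objects(plane, mask = plane > 0, units = "pixel",
                          area_filter = c(0, Inf), radius_filter = c(0, Inf))
  expect_identical(nrow(recs), 2L)
})

test_that("the literal peak-comparison rule is available as a switch", {
  # deep saddle but similar peaks: saddle rule splits, peak rule merges
  vals <- c(100, 10, 90)
  plane <- matrix(vals, nrow = 1)
  msk <- matrix(TRUE, 1, 3)
  n_saddle <- nrow(segment_objects(plane, mask = msk, units = "pixel",
                                   area_filter = c(0, Inf),
                                   radius_filter = c(0, Inf)))
  n_peak <- nrow(segment_objects(plane, mask = msk, split_rule = "peak",
                                 units = "pixel", area_filter = c(0, Inf),
                                 radius_filter = c(0, Inf)))
  expect_identical(n_saddle, 2L)
  expect_identical(n_peak, 1L)    # peaks within 50% of each other
  # dissimilar peaks: peak rule separates
  vals2 <- c(100, 10, 40)
  n_peak2 <- nrow(segment_objects(matrix(vals2, 1), mask = msk,
                                  split_rule = "peak", units = "pixel",
                                  area_filter = c(0, Inf),
                                  radius_filter = c(0, Inf)))
  expect_identical(n_peak2, 2L)
})

test_that("segmentation matches the brute-force oracle across a
          double-Gaussian sweep", {
  for (a2 in c(250, 500, 1000)) {
    for (sep in c(4, 6, 8, 11)) {
      img <- double_gaussian_plane(n = 32, a1 = 1000, a2 = a2, sep = sep,
                                   sigma = 2)
      mask <- img >= 50
      expected <- oracle_object_count(img, mask, frac = 0.5)
      recs <- segment_objects(img, mask = mask, units = "pixel",
                              area_filter = c(0, Inf),
                              radius_filter = c(0, Inf))
      expect_identical(nrow(recs), as.integer(expected),
                       info = sprintf("a2=%g sep=%g", a2, sep))
    }
  }
})

test_that("segmentation labels agree with BFS connected components when no
          splitting occurs", {
  withr::with_seed(11, {
    for (trial in 1:5) {
      img <- matrix(runif(16 * 16), 16, 16)
      mask <- img > 0.6
      # merge-always variant (saddle_frac 0) equals plain components
      recs <- segment_objects(img, mask = mask, saddle_frac = 0,
                              units = "pixel", area_filter = c(0, Inf),
                              radius_filter = c(0, Inf))
      expect_identical(nrow(recs),
                       max(oracle_components(mask)))
    }
  })
})

test_that("morphometry filters discard with reasons and calibrated units", {
  # one 2x2 punctum: area 4 px = 0.16 um^2 at 0.2 um pixels
  plane <- matrix(0, 16, 16)
  plane[8:9, 8:9] <- 100
  recs <- segment_objects(plane, mask = plane > 0, pixel_size = 0.2,
                          units = "um")
  expect_identical(nrow(recs), 0L)
  disc <- attr(recs, "discarded")
  expect_identical(disc$reason, "area")
  expect_equal(disc$area, 4 * 0.2^2)
  # the same object in pixel units passes the 10-1500 filter? 4 px < 10 -> no
  recs_px <- segment_objects(plane, mask = plane > 0, units = "pixel")
  expect_identical(nrow(recs_px), 0L)
  # larger punctum in pixel units is retained with outer radius in px
  plane2 <- matrix(0, 16, 16)
  plane2[5:10, 5:10] <- 100
  recs2 <- segment_objects(plane2, mask = plane2 > 0, units = "pixel")
  expect_identical(nrow(recs2), 1L)
  expect_equal(recs2$n_pixels, 36)
  expect_equal(recs2$outer_radius, sqrt(2) * 2.5, tolerance = 1e-9)
  # calibrated mode requires a pixel size
  expect_error(segment_objects(plane2, mask = plane2 > 0), "pixel_size")
})
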