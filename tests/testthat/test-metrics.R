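test_that("five-pixel rate uses a strict inequality", {
  expect_equal(five_pixel_rate(c(0, 1, 2, 3, 4)), 1.0)
  expect_equal(five_pixel_rate(c(5, 6)), 0.0)
  expect_equal(five_pixel_rate(c(4.9, 5.0, 1.0, 10.0)), 0.5)
  expect_equal(five_pixel_rate(c(1, NA, 10)), 0.5)  # NA excluded from denominator
  expect_equal(five_pixel_rate(c(1, Inf)), 0.5)     # failed detection counts wrong
  expect_error(five_pixel_rate(NA_real_), "no defined errors")
})

test_that("pooled precision sums TP and FP across batches", {
  expect_equal(precision(9, 1), 0.9)
  expect_equal(precision(c(4, 4), c(0, 0)), 1.0)
  expect_equal(precision(c(3, 2), c(1, 4)), 0.5)
  expect_error(precision(0, 0), "undefined")
  expect_error(precision(-1, 2), "nonnegative")
})

test_that("rmse matches closed forms for scalars and 2-D points", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(0, 3), 3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(rbind(c(0, 0), c(1, 1)), rbind(c(3, 4), c(1, 1))),
               sqrt(25 / 2))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("rmse dominates the max residual over sqrt(n)", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_gte(rmse(a, b) + 1e-12, max(abs(a - b)) / sqrt(n))
  }
})

test_that("angular error matches geometry and its invariances", {
  expect_equal(angular_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_error(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(angular_error(c(0, 0, 0), c(1, 0, 0)), "nonzero")
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(angular_error(a, b), angular_error(b, a))
    expect_equal(angular_error(3.7 * a, b), angular_error(a, b))
  }
})

test_that("screen points convert to gaze vectors under the stated geometry", {
  geom <- list(px_per_mm = 1, viewing_distance_mm = 1000, center_px = c(320, 240))
  ctr <- gaze_angles_from_screen(c(320, 240), geom)
  expect_equal(unname(ctr[1, ]), c(0, 0, 1))
  # 1000 mm off-center at 1000 mm distance: 45 degrees off the normal
  off <- gaze_angles_from_screen(c(320 + 1000, 240), geom)
  expect_equal(angular_error(off[1, ], c(0, 0, 1)), 45)
  # 17.45 mm at 1 m is about one degree
  one <- gaze_angles_from_screen(c(320 + 17.45, 240), geom)
  expect_equal(angular_error(one[1, ], c(0, 0, 1)), 1, tolerance = 1e-3)
  geom$viewing_distance_mm <- 0
  expect_error(gaze_angles_from_screen(c(0, 0), geom), "positive")
})

test_that("localization error is the Euclidean distance", {
  expect_equal(localization_error(c(0, 0), c(0, 0)), 0)
  expect_equal(localization_error(c(0, 0), c(3, 4)), 5)
  expect_equal(localization_error(c(1, 1), c(4, 5)), 5)
  expect_equal(localization_error(rbind(c(0, 0), c(1, 1)), rbind(c(3, 4), c(1, 1))),
               c(5, 0))
})

test_that("cross-validation behaves across noise regimes", {
  tm <- default_mapping_model()
  s0 <- generate_gaze_session(tm, 30, noise_sigma = 0, seed = 13)
  cv0 <- cross_validate(s0, 5, order = 2, seed = 1)
  expect_lt(cv0$mean_rmse, 1e-6)

  s12 <- generate_gaze_session(tm, 12, noise_sigma = 0, seed = 14)
  cv_loo <- cross_validate(s12, 12, order = 2, seed = 1)  # leave-one-out
  expect_identical(nrow(cv_loo$per_fold), 12L)

  # 2 px noise on each pupil coordinate through a near-unit Jacobian gives a
  # Euclidean (two-component) residual RMSE near sqrt(2) * 2 px
  s2 <- generate_gaze_session(tm, 500, noise_sigma = 2, seed = 15)
  cv2 <- cross_validate(s2, 5, order = 2, seed = 1)
  expect_gt(cv2$mean_rmse, sqrt(2) * 2 * 0.85)
  expect_lt(cv2$mean_rmse, sqrt(2) * 2 * 1.15)

  expect_error(cross_validate(s12, 1, order = 2), ">= 2")
  s6 <- generate_gaze_session(tm, 7, noise_sigma = 0, seed = 16)
  expect_error(cross_validate(s6, 2, order = 2, seed = 1), "fewer than m")
})
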