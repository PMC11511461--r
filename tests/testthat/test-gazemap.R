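test_that("coefficient counts follow the closed form", {
  expect_identical(coefficient_count(1), 3L)
  expect_identical(coefficient_count(2), 6L)
  expect_identical(coefficient_count(3), 10L)  # = monomials of degree <= 3
  expect_error(coefficient_count(0), ">= 1")
})

test_that("six noiseless points recover the generating second-order model", {
  tm <- default_mapping_model()
  s <- generate_gaze_session(tm, 6, noise_sigma = 0, seed = 2)
  fit <- gaze_fit(s, order = 2)
  expect_lt(max(abs(fit$A - tm$A) / pmax(abs(tm$A), 1e-12)), 1e-8)
  expect_lt(max(abs(fit$B - tm$B) / pmax(abs(tm$B), 1e-12)), 1e-8)
})

test_that("identity data yields the identity coefficients", {
  set.seed(3)
  xy <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  fit <- gaze_fit(calibration_set(xy, xy), order = 2)
  expect_equal(fit$A, c(0, 1, 0, 0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$B, c(0, 0, 1, 0, 0, 0), tolerance = 1e-8)
})

test_that("degenerate calibration geometry is rejected", {
  xy <- cbind(1:6, 2 * (1:6) + 3)  # collinear pupil vectors
  uv <- cbind(1:6, 1:6)
  expect_error(gaze_fit(calibration_set(xy, uv), order = 2), "rank deficient")
  expect_error(gaze_fit(calibration_set(xy[1:4, ], uv[1:4, ]), order = 2),
               "at least m = 6")
})

test_that("prediction evaluates the polynomials exactly", {
  zero <- mapping_model(rep(0, 6), rep(0, 6), 2)
  expect_equal(unname(gaze_predict(zero, c(10, 20))[1, ]), c(0, 0))
  m <- mapping_model(c(1, 0, 0, 1, 0, 0), rep(0, 6), 2)
  expect_equal(gaze_predict(m, c(2, 77))[1, "u"], c(u = 5))  # 1 + 2^2
})

test_that("fit/predict round-trips a noiseless session", {
  tm <- default_mapping_model()
  s <- generate_gaze_session(tm, 25, noise_sigma = 0, seed = 8)
  fit <- gaze_fit(s, order = 2)
  expect_equal(unname(gaze_predict(fit, s$pupil)), unname(s$screen),
               tolerance = 1e-6)
})

test_that("the overdetermined fit is least-squares optimal", {
  tm <- default_mapping_model()
  s <- generate_gaze_session(tm, 40, noise_sigma = 2, seed = 4)
  fit <- gaze_fit(s, order = 2)
  rss <- function(model) sum((gaze_predict(model, s$pupil) - s$screen)^2)
  base <- rss(fit)
  set.seed(5)
  for (i in 1:20) {
    pert <- mapping_model(fit$A + rnorm(6, 0, 1e-4 * pmax(abs(fit$A), 1e-3)),
                          fit$B + rnorm(6, 0, 1e-4 * pmax(abs(fit$B), 1e-3)), 2)
    expect_gte(rss(pert), base)
  }
})

test_that("second-order data punishes a first-order fit", {
  # strong quadratic component so the model-order gap is unambiguous
  tm <- mapping_model(A = c(20, 0.9, 0.05, 8e-4, 4e-4, -2e-4),
                      B = c(15, -0.03, 0.85, 2e-4, 6e-4, 4e-4), 2)
  s <- generate_gaze_session(tm, 100, noise_sigma = 0.5, seed = 6,
                             pupil_box = c(100, 450, 100, 380),
                             display_bounds = c(0, 900, 0, 700))
  cv1 <- cross_validate(s, 5, order = 1, seed = 7)
  cv2 <- cross_validate(s, 5, order = 2, seed = 7)
  expect_gt(cv1$mean_rmse, cv2$mean_rmse)
})

test_that("the six-point target layout is in general position", {
  tgt <- calibration_targets()
  M <- pupilgaze:::design_matrix(tgt, 2)
  expect_identical(qr(M)$rank, 6L)
})
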