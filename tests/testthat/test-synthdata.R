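test_that("generated frames satisfy the basic contracts", {
  cfg <- messy_synth()
  for (seed in c(1, 7, 23)) {
    fr <- generate_eye_frame(cfg, seed)
    expect_s3_class(fr, "eye_frame")
    expect_true(all(fr$pixels >= 0 & fr$pixels <= 1))
    expect_identical(dim(fr$pixels), c(64L, 64L))
    a <- fr$annotation
    expect_gte(a$semi_axes[1], a$semi_axes[2])
    expect_true(a$orientation >= 0 && a$orientation < pi)
    expect_true(all(a$center >= 0 & a$center <= 63))
    if (a$closed) expect_false(any(a$mask))
  }
})

test_that("same seed gives bit-identical frames", {
  cfg <- messy_synth()
  f1 <- generate_eye_frame(cfg, 7)
  f2 <- generate_eye_frame(cfg, 7)
  expect_identical(f1, f2)
  f3 <- generate_eye_frame(cfg, 8)
  expect_false(identical(f1$pixels, f3$pixels))
})

test_that("closed-eye probability 1 forces closed frames with empty masks", {
  cfg <- messy_synth(closed_prob = 1)
  for (seed in 1:5) {
    fr <- generate_eye_frame(cfg, seed)
    expect_true(fr$annotation$closed)
    expect_false(any(fr$annotation$mask))
  }
})

test_that("clean-frame mask matches the brute-force ellipse rasterization", {
  cfg <- tiny_synth()
  fr <- generate_eye_frame(cfg, 11)
  a <- fr$annotation
  n_oracle <- ellipse_count_oracle(64, 64, a$center, a$semi_axes, a$orientation)
  expect_identical(sum(a$mask), n_oracle)
})

test_that("nuisance rendering never corrupts the annotation", {
  # the stored mask must re-rasterize exactly from the stored ellipse even on
  # frames full of glints, occlusion, gradients and noise
  cfg <- messy_synth(closed_prob = 0)
  for (seed in 1:6) {
    a <- generate_eye_frame(cfg, seed)$annotation
    remask <- rasterize_ellipse(64, 64, a$center, a$semi_axes, a$orientation)
    expect_identical(a$mask, remask)
  }
})

test_that("open-eye mask centroid sits within 0.5 px of the annotated center", {
  cfg <- messy_synth(closed_prob = 0)
  for (seed in 1:10) {
    a <- generate_eye_frame(cfg, seed)$annotation
    idx <- which(a$mask)
    xs <- (idx - 1) %/% 64; ys <- (idx - 1) %% 64
    expect_lt(sqrt((mean(xs) - a$center[1])^2 + (mean(ys) - a$center[2])^2), 0.5)
  }
})

test_that("oversized pupils and bad geometries are rejected", {
  expect_error(tiny_synth(pupil_radius_range = c(10, 40)),
               "half the image")
  expect_error(synth_eye_config(width = 50), "divisible by 16")
  expect_error(synth_eye_config(height = 16), ">= 32")
})

test_that("dataset split is 70/15/15 with remainder to training", {
  cfg <- tiny_synth()
  ds <- generate_dataset(cfg, 100, seed = 1)
  expect_identical(lengths(ds$split), c(train = 70L, val = 15L, test = 15L))
  expect_identical(sort(unname(unlist(ds$split))), 1:100)

  ds10 <- generate_dataset(cfg, 10, seed = 1)
  expect_identical(lengths(ds10$split), c(train = 8L, val = 1L, test = 1L))

  expect_error(generate_dataset(cfg, 9, seed = 1), ">= 10")

  # stable assignment: same seed reproduces the split
  expect_identical(ds$split, generate_dataset(cfg, 100, seed = 1)$split)
})

test_that("gaze sessions honor the generating model", {
  ident <- mapping_model(A = c(0, 1, 0, 0, 0, 0), B = c(0, 0, 1, 0, 0, 0), 2)
  s <- generate_gaze_session(ident, 20, noise_sigma = 0, seed = 3,
                             pupil_box = c(50, 400, 50, 400),
                             display_bounds = c(0, 640, 0, 480))
  expect_equal(unname(s$pupil), unname(s$screen), tolerance = 1e-12)

  tm <- default_mapping_model()
  s2 <- generate_gaze_session(tm, 40, noise_sigma = 0, seed = 5)
  expect_equal(unname(s2$screen), unname(gaze_predict(tm, s2$pupil)),
               tolerance = 1e-12)
  expect_true(all(s2$screen[, 1] >= 0 & s2$screen[, 1] <= 640))

  expect_error(generate_gaze_session(tm, 5, seed = 1), "under-determined")
})

test_that("session noise propagates to screen residuals at the stated scale", {
  tm <- default_mapping_model()
  s <- generate_gaze_session(tm, 500, noise_sigma = 2, seed = 9)
  resid <- s$screen - gaze_predict(tm, s$pupil)
  # near-unit Jacobian: pooled residual sd within 15% of the 2 px input noise
  expect_lt(abs(sd(as.numeric(resid)) - 2) / 2, 0.15)
})
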