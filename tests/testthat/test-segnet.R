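test_that("the gate implements the Heaviside rule with H(0) = 1", {
  expect_identical(gate(0.0, 0.01), 1L)
  expect_identical(gate(1.0, 0.01), 0L)
  expect_identical(gate(0.99, 0.01), 1L)  # boundary: H(0) = 1
  expect_identical(gate(0.995, 0.01), 0L)
  expect_identical(gate(c(0, 0.5, 1), 0.1), c(1L, 1L, 0L))
  expect_error(gate(1.2, 0.01), "\\[0, 1\\]")
  expect_error(gate(0.5, -0.1), "\\[0, 1\\]")
})

test_that("network configuration invariants are enforced", {
  expect_error(net_config(carafe_r = 4), "must be 2")
  expect_error(net_config(carafe_m = 4), "odd")
  expect_error(net_config(channel_multipliers = c(1, 2)), "length 5")
  expect_error(net_config(loss_weights = c(0, 0)), "positive sum")
  expect_error(net_config(epsilon = 1.5), "\\(0, 1\\)")
})

test_that("Dice loss matches its closed forms", {
  y <- matrix(0, 8, 8); y[3:6, 3:6] <- 1
  expect_equal(dice_loss(y, y), 0)
  y2 <- matrix(0, 8, 8); y2[1:2, 1:2] <- 1
  expect_equal(dice_loss(y, y2), 1)
  # truth all ones over N pixels, prediction 1 on exactly N/2 -> 1/3
  yy <- matrix(1, 4, 8)
  pp <- matrix(0, 4, 8); pp[, 1:4] <- 1
  expect_equal(dice_loss(yy, pp), 1 / 3)
  # degenerate empty/empty case is defined as 0
  expect_equal(dice_loss(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "same shape")
})

test_that("closure BCE matches its closed forms", {
  expect_equal(closure_loss(0, 0.5), log(2))
  expect_equal(closure_loss(1, 0.5), log(2))
  expect_lt(closure_loss(1, 1 - 1e-7), 1e-6)
  expect_true(is.finite(closure_loss(1, 0)))  # clipping keeps it finite
})

test_that("total loss is linear and masks the pupil term when gated off", {
  expect_equal(total_loss(0.2, 0.3, 1, 1), 0.5)
  expect_equal(total_loss(0.2, 0.3, 0, 2), 0.6)
  expect_equal(total_loss(0.9, 0.3, 1, 0.5, gate = 0L), 0.15)
})

test_that("forward pass conserves shape and rejects non-divisible inputs", {
  net <- net_init(small_net_config(), seed = 1)
  fr <- generate_eye_frame(tiny_synth(), seed = 3)
  out <- segnet_forward(fr, net)
  expect_identical(dim(out$prob_map), dim(fr$pixels))
  expect_true(all(out$prob_map >= 0 & out$prob_map <= 1))
  expect_error(segnet_forward(matrix(0.5, 60, 64), net), "divisible by 16")

  # non-square but 16-divisible input works
  out2 <- segnet_forward(matrix(0.5, 32, 48), net)
  expect_identical(dim(out2$prob_map), c(32L, 48L))
})

test_that("forward gating is consistent with the Heaviside rule", {
  cfg <- small_net_config(epsilon = 0.2)
  net <- net_init(cfg, seed = 2)
  fr <- generate_eye_frame(tiny_synth(), seed = 4)
  # sweep the closure-head bias to drive Pclose across the gate boundary
  for (bias in c(-6, -1, 0, 1, 6)) {
    net$params[["head.W"]][] <- 0
    net$params[["head.b"]] <- bias
    out <- segnet_forward(fr, net)
    expect_equal(out$p_close, stats::plogis(bias), tolerance = 1e-12)
    expect_identical(out$gate, gate(out$p_close, cfg$epsilon))
    expect_identical(out$decoder_ran, out$gate == 1L)
    if (out$gate == 0L) expect_true(all(out$prob_map == 0))
  }
})

test_that("default configuration stays within the 1.2 MB footprint", {
  fp <- net_parameter_count(net_config())
  expect_lte(fp$bytes, 1.2 * 2^20)
  expect_gt(fp$bytes, 2^18)  # and is not trivially small
})

test_that("analytic gradients match numerical differentiation end to end", {
  # full network (encoder, closure head, CARAFE decoder, skips, joint loss)
  # on a 16x16 batch of one open and one closed frame
  cfg <- net_config(base_channels = 2L, channel_multipliers = c(1, 1, 1, 1, 1),
                    carafe_m = 3L)
  net <- net_init(cfg, seed = 5)
  set.seed(6)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  mask <- matrix(0, 16, 16); mask[5:9, 6:11] <- 1
  closed <- c(FALSE, TRUE)
  lam <- cfg$loss_weights

  loss_of <- function(net) {
    fwd <- pupilgaze:::net_fwd(x, net, training = TRUE, decode_idx = 1L)
    d <- dice_loss(mask, fwd$probs[, , 1, 1])
    b <- closure_loss(as.numeric(closed), fwd$p_close)
    lam[1] * d + lam[2] * b
  }
  fwd <- pupilgaze:::net_fwd(x, net, training = TRUE, decode_idx = 1L)
  dw <- pupilgaze:::dice_with_grad(mask, fwd$probs[, , 1, 1])
  dprobs <- array(lam[1] * dw$grad, dim(fwd$probs))
  dprobs <- dprobs * fwd$probs * (1 - fwd$probs)
  dlogit <- lam[2] * (fwd$p_close - as.numeric(closed)) / 2
  grads <- pupilgaze:::net_bwd(fwd, net, dprobs, dlogit)

  set.seed(7)
  keys <- c("enc1.c1.W", "enc3.c2.g", "enc5.c4.be", "car2.W", "dec1.c1.W",
            "dec4.c4.b", "head.W", "out.W")
  for (key in keys) {
    i <- sample(length(net$params[[key]]), 1)
    eps <- 1e-5
    np <- net; np$params[[key]][i] <- np$params[[key]][i] + eps
    nm <- net; nm$params[[key]][i] <- nm$params[[key]][i] - eps
    gnum <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    expect_equal(grads[[key]][i], gnum, tolerance = 1e-4,
                 label = sprintf("analytic grad of %s[%d]", key, i))
  }
})

test_that("a few Adam steps on one batch reduce the joint loss", {
  cfg <- net_config(base_channels = 2L, channel_multipliers = c(1, 1, 2, 2, 2))
  frames <- lapply(1:8, function(s) generate_eye_frame(messy_synth(), s))
  fit <- train_segnet(frames, cfg, train_config(epochs = 4, batch_size = 8, seed = 1))
  expect_lt(tail(fit$log$total, 1), fit$log$total[1])
  expect_identical(nrow(fit$log), 4L)
})

test_that("checkpoints round-trip through disk", {
  net <- net_init(small_net_config(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  net2 <- load_checkpoint(path)
  expect_equal(net, net2)
  fr <- generate_eye_frame(tiny_synth(), seed = 1)
  expect_identical(segnet_forward(fr, net), segnet_forward(fr, net2))
})
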