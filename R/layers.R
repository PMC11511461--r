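# Differentiable layer primitives on [H, W, C, N] arrays. Each *_fwd returns
# list(out, cache); each *_bwd consumes the upstream gradient and the cache.
# Hot inner loops (im2col conv, pooling, CARAFE) live in src/ops.cpp.

conv_fwd <- function(x, W, b, pad) {
  out <- cpp_conv2d_fwd(x, W, b, pad)
  list(out = out, cache = list(x = x, W = W, pad = pad))
}

conv_bwd <- function(dout, cache) {
  g <- cpp_conv2d_bwd(cache$x, cache$W, dout, cache$pad)
  list(dx = g$dx, dW = g$dw, db = g$db)
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(out = x, cache = list(neg = neg, slope = slope))
}

lrelu_bwd <- function(dout, cache) {
  dout[cache$neg] <- dout[cache$neg] * cache$slope
  dout
}

# batch normalization over (H, W, N) per channel
bn_fwd <- function(x, gamma, beta, training, run_mean, run_var,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    s <- matrix(.colSums(x, HW, C * N), C, N)
    mu <- rowSums(s) / (HW * N)
    s2 <- matrix(.colSums(x * x, HW, C * N), C, N)
    v <- rowSums(s2) / (HW * N) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  mu_f <- rep(rep(mu, each = HW), times = N)
  sd_f <- rep(rep(inv_sd, each = HW), times = N)
  xhat <- (x - mu_f) * sd_f
  g_f <- rep(rep(gamma, each = HW), times = N)
  b_f <- rep(rep(beta, each = HW), times = N)
  out <- xhat * g_f + b_f
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dims = d),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dout, cache) {
  d <- cache$dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- HW * N
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(.colSums(dout * xhat, HW, C * N), C, N))
  dbeta <- rowSums(matrix(.colSums(dout, HW, C * N), C, N))
  g_f <- rep(rep(cache$gamma, each = HW), times = N)
  dxhat <- dout * g_f
  sum_dxhat <- rowSums(matrix(.colSums(dxhat, HW, C * N), C, N))
  sum_dxhat_xhat <- rowSums(matrix(.colSums(dxhat * xhat, HW, C * N), C, N))
  t1 <- rep(rep(sum_dxhat / M, each = HW), times = N)
  t2 <- rep(rep(sum_dxhat_xhat / M, each = HW), times = N)
  sd_f <- rep(rep(cache$inv_sd, each = HW), times = N)
  dx <- sd_f * (dxhat - t1 - xhat * t2)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}
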