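# Shared fixtures: everything is generated in code, nothing on disk.

# small, fast frame generator configuration (16-divisible, clean by default)
tiny_synth <- function(...) {
  args <- utils::modifyList(list(
    width = 64L, height = 64L, pupil_radius_range = c(6, 12),
    closed_prob = 0, glint_count_range = c(0L, 0L),
    illum_range = c(0, 0), noise_sd = 0
  ), list(...))
  do.call(synth_eye_config, args)
}

# a noisy, cluttered configuration exercising every nuisance feature
messy_synth <- function(...) {
  args <- utils::modifyList(list(
    width = 64L, height = 64L, pupil_radius_range = c(5, 14),
    closed_prob = 0.15, glint_count_range = c(1L, 3L),
    illum_range = c(0.05, 0.3), noise_sd = 0.03
  ), list(...))
  do.call(synth_eye_config, args)
}

small_net_config <- function(...) {
  do.call(net_config, utils::modifyList(list(base_channels = 2L), list(...)))
}

# independent brute-force oracle for content-aware reassembly (triple loop)
carafe_oracle <- function(x, K, m, r) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  c0 <- (m - 1) / 2
  out <- array(0, c(H * r, W * r, C))
  for (u in 0:(H * r - 1)) for (v in 0:(W * r - 1)) {
    s <- u %/% r; t <- v %/% r
    for (i in 0:(m - 1)) for (j in 0:(m - 1)) {
      si <- s + i - c0; tj <- t + j - c0
      if (si >= 0 && si < H && tj >= 0 && tj < W) {
        out[u + 1, v + 1, ] <- out[u + 1, v + 1, ] +
          K[j * m + i + 1, u + 1, v + 1] * x[si + 1, tj + 1, ]
      }
    }
  }
  out
}

# independent pixel-counting oracle for the ellipse inequality
ellipse_count_oracle <- function(width, height, center, axes, theta) {
  n <- 0L
  for (yy in 0:(height - 1)) for (xx in 0:(width - 1)) {
    dx <- xx - center[1]; dy <- yy - center[2]
    u <- (dx * cos(theta) + dy * sin(theta)) / axes[1]
    v <- (-dx * sin(theta) + dy * cos(theta)) / axes[2]
    if (u^2 + v^2 <= 1) n <- n + 1L
  }
  n
}

random_kernels <- function(m, rH, rW, seed = 1) {
  set.seed(seed)
  K <- array(stats::runif(m * m * rH * rW), c(m * m, rH, rW))
  sums <- apply(K, c(2, 3), sum)
  K / rep(sums, each = m * m)
}
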