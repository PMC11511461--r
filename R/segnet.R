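#' Configuration of the gated pupil-segmentation network
#'
#' The network is a compact U-shaped encoder-decoder: five down blocks of
#' four 3x3 convolutions each (batch norm + LeakyReLU), a 2x2 average pool
#' after each of the first four, so the bottleneck sits at 1/16 of the input
#' resolution. An eye-closure head (global average pool + linear + sigmoid)
#' reads the bottleneck and produces `Pclose`; the decoder of four up blocks
#' (CARAFE x2 upsampling, skip connection from the matching encoder stage,
#' four convolutions) only runs when the gate
#' `G = Heaviside(1 - Pclose - epsilon)` is 1. Default channel widths keep
#' the float32 parameter footprint close to 1 MB.
#'
#' @param base_channels width of the first encoder block.
#' @param channel_multipliers five integers; encoder block widths are
#'   `base_channels * channel_multipliers`.
#' @param carafe_m odd CARAFE kernel size.
#' @param carafe_r CARAFE upsampling ratio; must be 2 so four up blocks undo
#'   four 2x2 poolings.
#' @param epsilon gating margin in (0, 1).
#' @param loss_weights `(lambda1, lambda2)` for the Dice and closure terms.
#' @param leaky_slope LeakyReLU negative slope in (0, 1).
#' @return object of class `net_config`.
#' @export
net_config <- function(base_channels = 8L, channel_multipliers = c(1, 2, 2, 4, 4),
                       carafe_m = 5L, carafe_r = 2L, epsilon = 0.01,
                       loss_weights = c(1, 0.5), leaky_slope = 0.01) {
  if (length(channel_multipliers) != 5) {
    stop("channel_multipliers must have length 5 (five down blocks)", call. = FALSE)
  }
  if (carafe_r != 2L) {
    stop("carafe_r must be 2: four up blocks x2 undo the 16x downsampling", call. = FALSE)
  }
  if (carafe_m %% 2 == 0 || carafe_m < 3) {
    stop("carafe_m must be odd and >= 3", call. = FALSE)
  }
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)", call. = FALSE)
  if (any(loss_weights < 0) || sum(loss_weights) <= 0) {
    stop("loss weights must be nonnegative with positive sum", call. = FALSE)
  }
  if (leaky_slope <= 0 || leaky_slope >= 1) {
    stop("leaky_slope must be in (0, 1)", call. = FALSE)
  }
  structure(list(base_channels = as.integer(base_channels),
                 channel_multipliers = as.integer(channel_multipliers),
                 carafe_m = as.integer(carafe_m), carafe_r = as.integer(carafe_r),
                 epsilon = epsilon, loss_weights = loss_weights,
                 leaky_slope = leaky_slope),
            class = "net_config")
}

#' Decoder gating variable
#'
#' `G = Heaviside(1 - p_close - epsilon)` with the convention
#' `Heaviside(0) = 1` (at the boundary the decoder still runs). `G = 1`
#' means the up-sampling branch executes; `G = 0` skips it entirely, which
#' is the blink shortcut that avoids pointless segmentation work.
#'
#' @param p_close eye-closure probability in `[0, 1]`.
#' @param epsilon gating margin in `[0, 1]`.
#' @return integer 0 or 1 (vectorized over `p_close`).
#' @export
gate <- function(p_close, epsilon) {
  stop_if_not_prob(p_close, "p_close")
  stop_if_not_prob(epsilon, "epsilon")
  as.integer(1 - p_close - epsilon >= 0)
}

#' Dice loss for pupil segmentation
#'
#' `1 - 2 sum(y * p) / (sum(y) + sum(p))`. The degenerate all-background case
#' (both sums zero) is defined as loss 0 via an additive smoothing constant
#' of 1; elsewhere the plain formula applies, so perfect overlap gives
#' exactly 0 and disjoint nonzero masks give exactly 1.
#'
#' @param truth_mask binary array/matrix.
#' @param pred_map probability array of the same shape, values in `[0, 1]`.
#' @return loss in `[0, 1]`.
#' @export
dice_loss <- function(truth_mask, pred_map) {
  if (!identical(dim(truth_mask), dim(pred_map)) &&
      length(truth_mask) != length(pred_map)) {
    stop("truth and prediction must have the same shape", call. = FALSE)
  }
  y <- as.numeric(truth_mask); p <- as.numeric(pred_map)
  sy <- sum(y); sp <- sum(p)
  if (sy + sp == 0) return(0)
  1 - 2 * sum(y * p) / (sy + sp)
}

#' Binary cross-entropy loss for eye-closure detection
#'
#' Standard BCE of the scalar closure label; the predicted probability is
#' clipped to `[1e-7, 1 - 1e-7]` so the loss is always finite.
#'
#' @param truth_closed 0/1 (or logical) true closure label.
#' @param p_close predicted closure probability.
#' @return loss `>= 0` (vector inputs give the mean).
#' @export
closure_loss <- function(truth_closed, p_close) {
  t <- as.numeric(truth_closed)
  p <- clip_prob(as.numeric(p_close))
  mean(-(t * log(p) + (1 - t) * log(1 - p)))
}

#' Joint training loss
#'
#' `lambda1 * dice + lambda2 * bce`. For a gated-off sample (`gate = 0`) no
#' decoder output exists, so the pupil term is masked to zero and only the
#' closure term contributes.
#'
#' @param dice Dice loss of the pupil map.
#' @param bce closure BCE loss.
#' @param lambda1,lambda2 nonnegative weights.
#' @param gate 0/1 decoder gate (default 1).
#' @return scalar loss.
#' @export
total_loss <- function(dice, bce, lambda1 = 1, lambda2 = 0.5, gate = 1L) {
  lambda1 * ifelse(gate == 1L, dice, 0) + lambda2 * bce
}

encoder_channels <- function(config) {
  config$base_channels * config$channel_multipliers
}

#' Initialize network weights
#'
#' He-normal convolution weights, unit batch-norm scales, zero biases. The
#' CARAFE kernel-predictor convolutions start at zero so the initial
#' upsampling is plain neighborhood averaging.
#'
#' @param config a [net_config()].
#' @param seed integer seed.
#' @param in_channels input image channels (1 for grayscale).
#' @return object of class `segnet` holding `params`, `bn` running stats and
#'   the config.
#' @export
net_init <- function(config, seed = 1L, in_channels = 1L) {
  ch <- encoder_channels(config)
  m <- config$carafe_m; r <- config$carafe_r
  with_seed(seed, {
    params <- list()
    bn <- list()
    add_block <- function(prefix, cin, cout) {
      for (j in 1:4) {
        ci <- if (j == 1) cin else cout
        params[[paste0(prefix, ".c", j, ".W")]] <<- he_init(3L, ci, cout)
        params[[paste0(prefix, ".c", j, ".b")]] <<- numeric(cout)
        params[[paste0(prefix, ".c", j, ".g")]] <<- rep(1, cout)
        params[[paste0(prefix, ".c", j, ".be")]] <<- numeric(cout)
        bn[[paste0(prefix, ".c", j)]] <<- list(mean = numeric(cout), var = rep(1, cout))
      }
    }
    cin <- in_channels
    for (d in 1:5) {
      add_block(paste0("enc", d), cin, ch[d])
      cin <- ch[d]
    }
    for (u in 1:4) {
      prev <- if (u == 1) ch[5] else ch[6 - u]
      p <- carafe_predictor_init(prev, m, r, k = 3L, zero = TRUE)
      params[[paste0("car", u, ".W")]] <- p$W
      params[[paste0("car", u, ".b")]] <- p$b
      add_block(paste0("dec", u), prev + ch[5 - u], ch[5 - u])
    }
    params[["head.W"]] <- matrix(rnorm(ch[5], 0, 1 / sqrt(ch[5])), 1, ch[5])
    params[["head.b"]] <- 0
    params[["out.W"]] <- he_init(1L, ch[1], 1L)
    # bias the output toward background: the pupil covers only a few percent
    # of the frame, and starting at that prior speeds Dice convergence
    params[["out.b"]] <- log(0.05 / 0.95)
    structure(list(params = params, bn = bn, config = config,
                   in_channels = as.integer(in_channels)),
              class = "segnet")
  })
}

#' Number of trainable parameters / serialized footprint
#'
#' @param net a `segnet` (or a [net_config()], which is initialized first).
#' @return list with `n_params` and `bytes` at 4 bytes (float32) per
#'   parameter.
#' @export
net_parameter_count <- function(net) {
  if (inherits(net, "net_config")) net <- net_init(net, seed = 1L)
  n <- sum(vapply(net$params, length, integer(1)))
  list(n_params = n, bytes = 4 * n)
}

# ---- internal batched forward / backward -----------------------------------

# four conv->BN->LeakyReLU layers; returns output + caches, updates bn state
block_fwd <- function(x, net, prefix, training, caches) {
  p <- net$params
  slope <- net$config$leaky_slope
  for (j in 1:4) {
    key <- paste0(prefix, ".c", j)
    cf <- conv_fwd(x, p[[paste0(key, ".W")]], p[[paste0(key, ".b")]], 1L)
    st <- net$bn[[key]]
    bf <- bn_fwd(cf$out, p[[paste0(key, ".g")]], p[[paste0(key, ".be")]],
                 training, st$mean, st$var)
    if (training) net$bn[[key]] <- list(mean = bf$run_mean, var = bf$run_var)
    lf <- lrelu_fwd(bf$out, slope)
    caches[[key]] <- list(conv = cf$cache, bn = bf$cache, lrelu = lf$cache)
    x <- lf$out
  }
  list(out = x, net = net, caches = caches)
}

block_bwd <- function(dout, net, prefix, caches, grads) {
  for (j in 4:1) {
    key <- paste0(prefix, ".c", j)
    cc <- caches[[key]]
    dout <- lrelu_bwd(dout, cc$lrelu)
    bb <- bn_bwd(dout, cc$bn)
    grads[[paste0(key, ".g")]] <- (grads[[paste0(key, ".g")]] %||% 0) + bb$dgamma
    grads[[paste0(key, ".be")]] <- (grads[[paste0(key, ".be")]] %||% 0) + bb$dbeta
    cb <- conv_bwd(bb$dx, cc$conv)
    grads[[paste0(key, ".W")]] <- (grads[[paste0(key, ".W")]] %||% 0) + cb$dW
    grads[[paste0(key, ".b")]] <- (grads[[paste0(key, ".b")]] %||% 0) + cb$db
    dout <- cb$dx
  }
  list(dx = dout, grads = grads)
}

# full forward pass on a batch x [H,W,C,N]; decode_idx selects the samples
# whose decoder branch runs (teacher-forced open frames during training,
# gate == 1 at inference). Returns probs only for decode_idx samples.
net_fwd <- function(x, net, training, decode_idx = NULL) {
  d <- dim(x)
  caches <- list()
  enc <- vector("list", 5)
  a <- x
  pool_caches <- vector("list", 4)
  for (dblk in 1:5) {
    bf <- block_fwd(a, net, paste0("enc", dblk), training, caches)
    net <- bf$net; caches <- bf$caches
    enc[[dblk]] <- bf$out
    if (dblk < 5) {
      pool_caches[[dblk]] <- dim(bf$out)
      a <- cpp_avgpool2_fwd(bf$out)
    }
  }
  bott <- enc[[5]]
  db <- dim(bott); HWb <- db[1] * db[2]
  gap <- matrix(.colSums(bott, HWb, db[3] * db[4]), db[3], db[4]) / HWb
  logit <- as.numeric(net$params[["head.W"]] %*% gap) + net$params[["head.b"]]
  p_close <- sigmoid(logit)

  if (is.null(decode_idx)) {
    decode_idx <- which(gate(p_close, net$config$epsilon) == 1L)
  }
  probs <- NULL; dec_caches <- NULL
  if (length(decode_idx) > 0) {
    m <- net$config$carafe_m; r <- net$config$carafe_r
    y <- bott[, , , decode_idx, drop = FALSE]
    dec_caches <- list(idx = decode_idx, stages = vector("list", 4))
    for (u in 1:4) {
      P <- cpp_conv2d_fwd(y, net$params[[paste0("car", u, ".W")]],
                          net$params[[paste0("car", u, ".b")]], 1L)
      K <- cpp_carafe_kernels(P, m, r)
      yup <- cpp_carafe_apply(y, K, m, r)
      skip <- enc[[5 - u]][, , , decode_idx, drop = FALSE]
      z <- concat_c(yup, skip)
      bf <- block_fwd(z, net, paste0("dec", u), training, caches)
      net <- bf$net; caches <- bf$caches
      dec_caches$stages[[u]] <- list(y = y, K = K, nup = dim(yup)[3])
      y <- bf$out
    }
    lf <- conv_fwd(y, net$params[["out.W"]], net$params[["out.b"]], 0L)
    caches[["out"]] <- lf$cache
    probs <- sigmoid(lf$out)
  }
  list(net = net, caches = caches, enc = enc, gap_dims = db,
       p_close = p_close, logit = logit, probs = probs,
       dec_caches = dec_caches, dims = d)
}

# backward pass; dprobs matches probs (decoded subset), dlogit_close is the
# per-sample gradient on the closure logit. Returns flat gradient list.
net_bwd <- function(fwd, net, dprobs, dlogit_close) {
  grads <- list()
  d <- fwd$dims
  denc <- vector("list", 5)  # gradient accumulators on encoder block outputs
  for (i in 1:5) denc[[i]] <- 0

  # closure head
  db <- fwd$gap_dims; HWb <- db[1] * db[2]
  gap <- matrix(.colSums(fwd$enc[[5]], HWb, db[3] * db[4]), db[3], db[4]) / HWb
  grads[["head.W"]] <- matrix(as.numeric(gap %*% dlogit_close), 1, db[3])
  grads[["head.b"]] <- sum(dlogit_close)
  dgap <- outer(as.numeric(net$params[["head.W"]]), dlogit_close)  # C x N
  dbott_head <- array(rep(as.numeric(dgap), each = HWb) / HWb, db)
  denc[[5]] <- denc[[5]] + dbott_head

  if (!is.null(fwd$dec_caches)) {
    idx <- fwd$dec_caches$idx
    m <- net$config$carafe_m; r <- net$config$carafe_r
    lb <- conv_bwd(dprobs, fwd$caches[["out"]])
    grads[["out.W"]] <- lb$dW; grads[["out.b"]] <- lb$db
    dy <- lb$dx
    for (u in 4:1) {
      bb <- block_bwd(dy, net, paste0("dec", u), fwd$caches, grads)
      grads <- bb$grads
      st <- fwd$dec_caches$stages[[u]]
      nup <- st$nup
      dz <- bb$dx
      dyup <- dz[, , seq_len(nup), , drop = FALSE]
      dskip <- dz[, , nup + seq_len(dim(dz)[3] - nup), , drop = FALSE]
      # scatter skip gradient into the full-batch encoder accumulator
      full <- array(0, dim(fwd$enc[[5 - u]]))
      full[, , , idx] <- dskip
      denc[[5 - u]] <- denc[[5 - u]] + full
      cb <- cpp_carafe_bwd(st$y, st$K, dyup, m, r)
      pb <- cpp_conv2d_bwd(st$y, net$params[[paste0("car", u, ".W")]], cb$dp, 1L)
      grads[[paste0("car", u, ".W")]] <- pb$dw
      grads[[paste0("car", u, ".b")]] <- pb$db
      dy <- cb$dx + pb$dx
    }
    full <- array(0, dim(fwd$enc[[5]]))
    full[, , , idx] <- dy
    denc[[5]] <- denc[[5]] + full
  }

  da <- denc[[5]]
  for (dblk in 5:1) {
    if (dblk < 5) {
      dd <- dim(fwd$enc[[dblk]])
      da <- cpp_avgpool2_bwd(da, dd[1], dd[2]) + denc[[dblk]]
    }
    bb <- block_bwd(da, net, paste0("enc", dblk), fwd$caches, grads)
    grads <- bb$grads
    da <- bb$dx
  }
  grads
}

#' Run the segmentation network on one eye frame
#'
#' Encoder and eye-closure head always run; the decoder only runs when the
#' gate `G = Heaviside(1 - Pclose - epsilon)` is 1. When gated off, the
#' probability map is the all-zero sentinel.
#'
#' @param frame an `eye_frame` or a plain `H x W` intensity matrix in `[0,1]`.
#' @param net a trained (or initialized) `segnet`.
#' @return a `seg_output`: list with `prob_map` (`H x W`), `p_close`,
#'   `gate` (0/1), `decoder_ran`.
#' @export
segnet_forward <- function(frame, net) {
  px <- if (inherits(frame, "eye_frame")) frame$pixels else frame
  h <- nrow(px); w <- ncol(px)
  if (h %% 16L != 0L || w %% 16L != 0L) {
    stop(sprintf("input size %dx%d rejected: both dimensions must be divisible by 16 (four 2x2 poolings)",
                 h, w), call. = FALSE)
  }
  x <- array(px, c(h, w, 1L, 1L))
  fwd <- net_fwd(x, net, training = FALSE)
  g <- gate(fwd$p_close, net$config$epsilon)
  prob_map <- if (g == 1L) matrix(fwd$probs, h, w) else matrix(0, h, w)
  structure(list(prob_map = prob_map, p_close = fwd$p_close,
                 gate = g, decoder_ran = g == 1L),
            class = "seg_output")
}
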