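#' Training hyperparameters
#'
#' Defaults follow the standard recipe for this model family: Adam with an
#' initial learning rate of 0.001, first/second moment decay rates 0.9 and
#' 0.999, batch size 8.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam decay rates.
#' @param seed integer seed controlling init order, shuffling and init noise.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# per-sample Dice loss and gradient on the probability map
dice_with_grad <- function(y, p) {
  sy <- sum(y); sp <- sum(p)
  if (sy + sp == 0) return(list(loss = 0, grad = p * 0))
  den <- sy + sp
  inter <- sum(y * p)
  loss <- 1 - 2 * inter / den
  grad <- -2 * y / den + 2 * inter / den^2
  list(loss = loss, grad = grad)
}

frames_to_batch <- function(frames) {
  h <- frames[[1]]$height; w <- frames[[1]]$width
  n <- length(frames)
  x <- array(0, c(h, w, 1L, n))
  for (i in seq_len(n)) x[, , 1L, i] <- frames[[i]]$pixels
  closed <- vapply(frames, function(f) f$annotation$closed, logical(1))
  masks <- lapply(frames, function(f) f$annotation$mask)
  list(x = x, closed = closed, masks = masks)
}

#' Train the gated segmentation network
#'
#' One Adam step per minibatch of the joint loss
#' `lambda1 * Dice + lambda2 * BCE`. During training the gate is
#' teacher-forced from the ground-truth closure label: the decoder (and the
#' Dice term) runs on open-eye frames only, closed frames contribute the
#' closure term. Inference ([segnet_forward()]) gates on the predicted
#' `Pclose` instead.
#'
#' @param frames list of annotated `eye_frame`s (the training split).
#' @param config a [net_config()].
#' @param tconf a [train_config()].
#' @param net optional `segnet` to resume from; a fresh one is initialized
#'   otherwise.
#' @param verbose print per-epoch losses.
#' @return list with `net` (trained `segnet`) and `log` (data.frame with one
#'   row per epoch: epoch, total, dice, bce).
#' @export
train_segnet <- function(frames, config = net_config(), tconf = train_config(),
                         net = NULL, verbose = FALSE) {
  if (length(frames) == 0) stop("no training frames supplied", call. = FALSE)
  if (is.null(net)) net <- net_init(config, seed = subseed(tconf$seed, 1L))
  config <- net$config
  lam <- config$loss_weights
  batch <- frames_to_batch(frames)
  n <- length(frames)
  state <- adam_init(net$params)
  log <- data.frame(epoch = integer(0), total = numeric(0),
                    dice = numeric(0), bce = numeric(0))
  if (tconf$epochs == 0L) return(list(net = net, log = log))
  with_seed(subseed(tconf$seed, 2L), {
    for (epoch in seq_len(tconf$epochs)) {
      ord <- sample.int(n)
      ep_tot <- 0; ep_dice <- 0; ep_bce <- 0; nb <- 0
      for (b0 in seq(1, n, by = tconf$batch_size)) {
        ids <- ord[b0:min(n, b0 + tconf$batch_size - 1)]
        xb <- batch$x[, , , ids, drop = FALSE]
        closed <- batch$closed[ids]
        open_idx <- which(!closed)
        fwd <- net_fwd(xb, net, training = TRUE, decode_idx = open_idx)
        net <- fwd$net

        # closure BCE on every sample; gradient on the logit is p - t
        t_close <- as.numeric(closed)
        bce <- closure_loss(t_close, fwd$p_close)
        dlogit <- lam[2] * (fwd$p_close - t_close) / length(ids)

        dice_mean <- 0
        dprobs <- NULL
        if (length(open_idx) > 0) {
          dprobs <- array(0, dim(fwd$probs))
          for (j in seq_along(open_idx)) {
            dw <- dice_with_grad(batch$masks[[ids[open_idx[j]]]],
                                 fwd$probs[, , 1, j])
            dice_mean <- dice_mean + dw$loss
            dprobs[, , 1, j] <- lam[1] * dw$grad / length(open_idx)
          }
          dice_mean <- dice_mean / length(open_idx)
          # through the output sigmoid
          dprobs <- dprobs * fwd$probs * (1 - fwd$probs)
        }
        grads <- net_bwd(fwd, net, dprobs, dlogit)
        up <- adam_step(net$params, grads, state, tconf$learning_rate,
                        tconf$beta1, tconf$beta2)
        net$params <- up$params
        state <- up$state
        ep_tot <- ep_tot + total_loss(dice_mean, bce, lam[1], lam[2])
        ep_dice <- ep_dice + dice_mean; ep_bce <- ep_bce + bce; nb <- nb + 1
      }
      log <- rbind(log, data.frame(epoch = epoch, total = ep_tot / nb,
                                   dice = ep_dice / nb, bce = ep_bce / nb))
      if (verbose) {
        message(sprintf("epoch %3d  total %.4f  dice %.4f  bce %.4f",
                        epoch, ep_tot / nb, ep_dice / nb, ep_bce / nb))
      }
    }
  })
  list(net = net, log = log)
}

#' Evaluate segmentation quality on annotated frames
#'
#' Runs inference ([segnet_forward()], predicted gating) on each frame and
#' scores it against the ground truth: Dice score (1 - Dice loss) on open
#' frames, closure-classification correctness, and the pupil-center pixel
#' error from [extract_pupil()].
#'
#' @param net a trained `segnet`.
#' @param frames list of annotated `eye_frame`s.
#' @param threshold probability threshold for pupil extraction.
#' @return data.frame with one row per frame: `frame_id`, `closed_truth`,
#'   `p_close`, `gate`, `dice`, `center_error`.
#' @export
evaluate_segnet <- function(net, frames, threshold = 0.5) {
  rows <- lapply(frames, function(f) {
    out <- segnet_forward(f, net)
    closed <- f$annotation$closed
    dice <- if (closed) NA_real_ else 1 - dice_loss(f$annotation$mask, out$prob_map)
    err <- NA_real_
    if (!closed) {
      st <- extract_pupil(out$prob_map, threshold)
      if (st$valid) {
        err <- pixel_error(st, f$annotation)
      } else {
        err <- Inf
      }
    }
    data.frame(frame_id = f$frame_id, closed_truth = closed,
               p_close = out$p_close, gate = out$gate, dice = dice,
               center_error = err, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
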