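#' Configuration for the synthetic near-infrared eye-image generator
#'
#' The generator emulates the look of head-mounted dark-pupil recordings:
#' a dark elliptical pupil inside a darker-than-skin iris disc, corneal
#' glints rendered as saturated discs, an occluding eyelid band, a linear
#' illumination gradient and additive Gaussian pixel noise. Intensities are
#' kept in `[0, 1]`. Defaults target the native eye-camera resolution
#' (640 x 480); tests use much smaller, 16-divisible sizes.
#'
#' @param width,height frame size in px; each must be >= 32 and divisible by
#'   16 so the encoder's four 2x2 poolings land on integral sizes.
#' @param pupil_radius_range range of the semi-major axis `a` in px.
#' @param aspect_range range of the axis ratio `b/a` (1 = circle).
#' @param closed_prob probability that a frame is a closed-eye (blink) frame.
#' @param glint_count_range integer range for the number of corneal glints.
#' @param glint_radius_range glint disc radius range in px.
#' @param illum_range amplitude range of the linear illumination gradient.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param pupil_intensity,iris_intensity,sclera_intensity intensity ranges of
#'   the dark-pupil contrast model.
#' @param open_lid_coverage maximum fraction of the pupil the eyelid may cover
#'   on a frame that still counts as open (frames at or above 90% coverage are
#'   labelled closed).
#' @param eye_side `"left"` or `"right"`, recorded in the frame metadata.
#' @return an object of class `synth_eye_config`.
#' @export
synth_eye_config <- function(width = 640, height = 480,
                             pupil_radius_range = c(20, 60),
                             aspect_range = c(0.6, 1),
                             closed_prob = 0.1,
                             glint_count_range = c(0L, 3L),
                             glint_radius_range = c(1, 4),
                             illum_range = c(0, 0.3),
                             noise_sd = 0.02,
                             pupil_intensity = c(0.05, 0.2),
                             iris_intensity = c(0.3, 0.6),
                             sclera_intensity = c(0.5, 0.9),
                             open_lid_coverage = 0.4,
                             eye_side = "left") {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              pupil_radius_range = pupil_radius_range,
              aspect_range = aspect_range, closed_prob = closed_prob,
              glint_count_range = as.integer(glint_count_range),
              glint_radius_range = glint_radius_range,
              illum_range = illum_range, noise_sd = noise_sd,
              pupil_intensity = pupil_intensity,
              iris_intensity = iris_intensity,
              sclera_intensity = sclera_intensity,
              open_lid_coverage = open_lid_coverage,
              eye_side = match.arg(eye_side, c("left", "right")))
  class(cfg) <- "synth_eye_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  for (d in c("width", "height")) {
    v <- cfg[[d]]
    if (v < 32L || v %% 16L != 0L) {
      stop(sprintf("%s must be >= 32 and divisible by 16, got %d", d, v),
           call. = FALSE)
    }
  }
  if (max(cfg$pupil_radius_range) > min(cfg$width, cfg$height) / 2) {
    stop("pupil radius range exceeds half the image size", call. = FALSE)
  }
  stop_if_not_prob(cfg$closed_prob, "closed_prob")
  if (cfg$open_lid_coverage >= 0.9) {
    stop("open_lid_coverage must stay below the 0.9 closed-eye threshold",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Rasterize an ellipse on the pixel grid
#'
#' Pixel centers sit at integer 0-based coordinates, `x` along columns and
#' `y` along rows. A pixel belongs to the ellipse when its center satisfies
#' the ellipse inequality.
#'
#' @param width,height grid size in px.
#' @param center `(cx, cy)` in px.
#' @param semi_axes `(a, b)` in px, `a >= b`.
#' @param orientation radians in `[0, pi)`, angle of the major axis.
#' @return a logical `height x width` matrix.
#' @export
rasterize_ellipse <- function(width, height, center, semi_axes, orientation) {
  xs <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  dx <- xs - center[1]
  dy <- ys - center[2]
  ct <- cos(orientation); st <- sin(orientation)
  u <- (dx * ct + dy * st) / semi_axes[1]
  v <- (-dx * st + dy * ct) / semi_axes[2]
  u * u + v * v <= 1
}

draw_disc <- function(img, center, radius, value) {
  h <- nrow(img); w <- ncol(img)
  xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  img[(xs - center[1])^2 + (ys - center[2])^2 <= radius^2] <- value
  img
}

#' Generate one synthetic near-infrared eye frame with exact ground truth
#'
#' The pupil ellipse and its binary mask are drawn first and frozen as the
#' annotation; eyelid occlusion, glints, the illumination gradient and noise
#' are rendered afterwards, so nuisance features never corrupt the ground
#' truth. A frame whose eyelid covers at least 90% of the pupil ellipse is
#' labelled closed and gets an all-zero mask.
#'
#' @param config a [synth_eye_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   frames.
#' @param frame_id optional identifier; defaults to `"synth_<seed>"`.
#' @return an `eye_frame`: list with `pixels` (height x width matrix in
#'   `[0,1]`), `height`, `width`, `annotation` (a `pupil_annotation`),
#'   `frame_id` and `eye_side`.
#' @export
generate_eye_frame <- function(config, seed, frame_id = NULL) {
  validate_synth_config(config)
  w <- config$width; h <- config$height
  with_seed(seed, {
    a <- runif(1, config$pupil_radius_range[1], config$pupil_radius_range[2])
    b <- a * runif(1, config$aspect_range[1], config$aspect_range[2])
    theta <- runif(1, 0, pi)
    margin <- a + 2
    cx <- runif(1, margin, w - 1 - margin)
    cy <- runif(1, margin, h - 1 - margin)
    closed_draw <- runif(1) < config$closed_prob

    sclera <- runif(1, config$sclera_intensity[1], config$sclera_intensity[2])
    iris <- runif(1, config$iris_intensity[1], config$iris_intensity[2])
    pupil <- runif(1, config$pupil_intensity[1], config$pupil_intensity[2])

    img <- matrix(sclera, nrow = h, ncol = w)
    img <- draw_disc(img, c(cx, cy), a * runif(1, 1.8, 2.6), iris)
    mask <- rasterize_ellipse(w, h, c(cx, cy), c(a, b), theta)
    img[mask] <- pupil

    # eyelid band: everything above lid_y is skin. On open frames the lid is
    # placed at a quantile of the pupil's row distribution so that coverage
    # stays below `open_lid_coverage`; on blink frames it drops past the
    # pupil's lower edge.
    pupil_rows <- ys_of_mask(mask)
    if (closed_draw) {
      lid_y <- min(h - 1, max(pupil_rows) + 2 + runif(1, 0, 4))
    } else {
      cover <- runif(1, 0, config$open_lid_coverage)
      lid_y <- if (cover <= 0) -1 else stats::quantile(pupil_rows, cover, names = FALSE)
    }
    coverage <- mean(pupil_rows <= lid_y)
    closed <- coverage >= 0.9
    if (lid_y >= 0) {
      rows <- seq_len(min(h, floor(lid_y) + 1))
      img[rows, ] <- sclera * 0.96
    }

    n_glint <- if (config$glint_count_range[2] > config$glint_count_range[1]) {
      sample(config$glint_count_range[1]:config$glint_count_range[2], 1)
    } else config$glint_count_range[1]
    if (n_glint > 0) {
      for (g in seq_len(n_glint)) {
        gx <- cx + runif(1, -1.5 * a, 1.5 * a)
        gy <- cy + runif(1, -1.5 * b, 1.5 * b)
        img <- draw_disc(img, c(gx, gy),
                         runif(1, config$glint_radius_range[1],
                               config$glint_radius_range[2]), 1.0)
      }
    }

    amp <- runif(1, config$illum_range[1], config$illum_range[2])
    if (amp > 0) {
      ang <- runif(1, 0, 2 * pi)
      xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
      ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
      ramp <- (cos(ang) * xs / max(1, w - 1) + sin(ang) * ys / max(1, h - 1))
      img <- img + amp * (ramp - mean(ramp))
    }
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, config$noise_sd), nrow = h)
    }
    img <- clip01(img)

    ann <- structure(list(
      center = c(cx, cy), semi_axes = c(a, b), orientation = theta,
      closed = closed,
      mask = if (closed) matrix(FALSE, h, w) else mask
    ), class = "pupil_annotation")
    structure(list(pixels = img, height = h, width = w, annotation = ann,
                   frame_id = frame_id %||% sprintf("synth_%d", as.integer(seed)),
                   eye_side = config$eye_side),
              class = "eye_frame")
  })
}

# 0-based row coordinates of mask pixels
ys_of_mask <- function(mask) {
  (which(mask) - 1) %% nrow(mask)
}

#' Generate a dataset of synthetic frames with a 70/15/15 split
#'
#' Validation and test sizes are floored at 15% of `n` each and the remainder
#' goes to training, so `n = 100` gives 70/15/15 and `n = 10` gives 8/1/1.
#' Assignment is a stable seeded permutation.
#'
#' @param config a [synth_eye_config()].
#' @param n number of frames, at least 10.
#' @param seed integer master seed.
#' @return list with `frames` (list of `eye_frame`) and `split` (list of
#'   integer index vectors `train`, `val`, `test`).
#' @export
generate_dataset <- function(config, n, seed) {
  if (n < 10) stop("n must be >= 10 so every split is non-empty", call. = FALSE)
  frames <- lapply(seq_len(n), function(i) {
    generate_eye_frame(config, subseed(seed, i),
                       frame_id = sprintf("synth_%05d", i))
  })
  n_val <- floor(0.15 * n)
  n_test <- floor(0.15 * n)
  perm <- with_seed(subseed(seed, 0L), sample.int(n))
  split <- list(train = sort(perm[seq_len(n - n_val - n_test)]),
                val = sort(perm[seq.int(n - n_val - n_test + 1, n - n_test)]),
                test = sort(perm[seq.int(n - n_test + 1, n)]))
  list(frames = frames, split = split)
}

#' Generate a synthetic calibration/gaze session
#'
#' Pupil-center vectors are sampled uniformly over a pupil-motion box in
#' eye-camera pixels, mapped through the generating polynomial model to
#' screen/scene coordinates, and Gaussian noise of sd `noise_sigma` is then
#' added to the pupil vectors (emulating pupil-detection jitter). With
#' `noise_sigma = 0` every pair satisfies the generating model exactly.
#'
#' @param true_model a [mapping_model()] of order 1 or 2.
#' @param n_points number of samples; must be at least the model's
#'   coefficient count `m`.
#' @param noise_sigma pupil-vector noise sd in px.
#' @param seed integer seed.
#' @param pupil_box `(xmin, xmax, ymin, ymax)` pupil-motion box in px.
#' @param display_bounds `(umin, umax, vmin, vmax)` screen bounds in px; the
#'   generated screen points must fall inside.
#' @return a `gaze_session`: list with `pupil` (n x 2), `screen` (n x 2),
#'   `true_model`, `noise_sigma`.
#' @export
generate_gaze_session <- function(true_model, n_points, noise_sigma = 0,
                                  seed = 1L,
                                  pupil_box = c(100, 500, 100, 400),
                                  display_bounds = c(0, 640, 0, 480)) {
  stopifnot(inherits(true_model, "mapping_model"))
  if (!true_model$order %in% c(1L, 2L)) {
    stop("generator supports mapping orders 1 and 2", call. = FALSE)
  }
  m <- coefficient_count(true_model$order)
  if (n_points < m) {
    stop(sprintf("n_points (%d) below coefficient count m = %d: downstream fit would be under-determined",
                 n_points, m), call. = FALSE)
  }
  with_seed(seed, {
    x <- runif(n_points, pupil_box[1], pupil_box[2])
    y <- runif(n_points, pupil_box[3], pupil_box[4])
    screen <- gaze_predict(true_model, cbind(x, y))
    if (any(screen[, 1] < display_bounds[1] | screen[, 1] > display_bounds[2] |
            screen[, 2] < display_bounds[3] | screen[, 2] > display_bounds[4])) {
      stop("generated screen points fall outside display bounds; shrink the pupil box or adjust the model",
           call. = FALSE)
    }
    pupil <- cbind(x + rnorm(n_points, 0, noise_sigma),
                   y + rnorm(n_points, 0, noise_sigma))
    colnames(pupil) <- c("x", "y")
    colnames(screen) <- c("u", "v")
    structure(list(pupil = pupil, screen = screen, true_model = true_model,
                   noise_sigma = noise_sigma,
                   display_bounds = display_bounds),
              class = "gaze_session")
  })
}

#' Default second-order generating model for synthetic sessions
#'
#' A near-identity mapping from the eye camera's pupil-motion box onto a
#' 640 x 480 scene image, with mild second-order distortion. The roughly unit
#' Jacobian keeps pupil-vector noise and screen-space residuals on the same
#' pixel scale.
#'
#' @return a [mapping_model()] of order 2.
#' @export
default_mapping_model <- function() {
  mapping_model(A = c(20, 1.02, 0.03, 8e-5, 5e-5, -6e-5),
                B = c(15, -0.02, 0.95, 4e-5, 8e-5, 6e-5),
                order = 2L)
}
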