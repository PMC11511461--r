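#' Write a grayscale image as plain-text PGM (P2)
#'
#' The environment carries no PNG codec, so frames and masks are exchanged
#' as 8-bit plain PGM, which every image tool reads. Intensities in `[0, 1]`
#' are scaled to 0..255.
#'
#' @param img numeric matrix in `[0, 1]` (or logical for masks).
#' @param path output file.
#' @export
write_pgm <- function(img, path) {
  v <- round(clip01(img * 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  # one image row per line
  writeLines(apply(v, 1, paste, collapse = " "), con)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path file written by [write_pgm()] (or any plain P2 PGM).
#' @return numeric matrix with intensities in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

#' Write frame annotations as CSV
#'
#' One row per frame: `frame_id, cx, cy, a, b, theta, closed`.
#'
#' @param frames list of annotated `eye_frame`s.
#' @param path output CSV.
#' @export
write_annotations <- function(frames, path) {
  rows <- lapply(frames, function(f) {
    a <- f$annotation
    data.frame(frame_id = f$frame_id, cx = a$center[1], cy = a$center[2],
               a = a$semi_axes[1], b = a$semi_axes[2], theta = a$orientation,
               closed = as.integer(a$closed), stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read a frame-annotation CSV
#' @param path CSV written by [write_annotations()].
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_id", "cx", "cy", "a", "b", "theta", "closed")
  if (!all(needed %in% names(df))) {
    stop("annotation CSV must carry columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write pupil measurements as CSV
#'
#' Columns: `frame_id, valid, closed, cx, cy, a, b, theta, diameter`.
#'
#' @param states named list of `pupil_state` (names are frame ids) or a list
#'   with `frame_id` attached.
#' @param path output CSV.
#' @export
write_pupil_csv <- function(states, path) {
  ids <- names(states) %||% as.character(seq_along(states))
  rows <- lapply(seq_along(states), function(i) {
    s <- states[[i]]
    data.frame(frame_id = ids[i], valid = as.integer(s$valid),
               closed = as.integer(s$closed),
               cx = s$center[1], cy = s$center[2],
               a = s$semi_axes[1], b = s$semi_axes[2],
               theta = s$orientation, diameter = s$diameter,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Save a mapping model as JSON
#' @param model a [mapping_model()].
#' @param path output file.
#' @export
write_mapping_model <- function(model, path) {
  jsonlite::write_json(list(order = model$order, A = model$A, B = model$B),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Load a mapping model from JSON
#' @param path file written by [write_mapping_model()].
#' @return a [mapping_model()].
#' @export
read_mapping_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mapping_model(A = j$A, B = j$B, order = j$order)
}

#' Write a calibration CSV (`point_id, x, y, u, v`)
#' @param calib a [calibration_set()] or `gaze_session`.
#' @param path output CSV.
#' @export
write_calibration_csv <- function(calib, path) {
  df <- data.frame(point_id = seq_len(nrow(calib$pupil)),
                   x = calib$pupil[, 1], y = calib$pupil[, 2],
                   u = calib$screen[, 1], v = calib$screen[, 2])
  write.csv(df, path, row.names = FALSE)
}

#' Read a calibration CSV
#' @param path CSV with columns `x, y, u, v`.
#' @return a [calibration_set()].
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  calibration_set(cbind(df$x, df$y), cbind(df$u, df$v))
}

#' Save a network checkpoint
#'
#' Weights and batch-norm state go to an RDS file; the network configuration
#' is mirrored into a human-readable JSON sidecar (`<path>.json`).
#'
#' @param net a `segnet`.
#' @param path checkpoint path (conventionally `*.rds`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `segnet`.
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "segnet"))
  net
}

#' Read a JSON run configuration
#'
#' The run configuration carries `synth`, `net`, `train`, `calib` and `eval`
#' blocks; omitted blocks and fields fall back to package defaults
#' ([synth_eye_config()], [net_config()], [train_config()]).
#'
#' @param path JSON file.
#' @return object of class `run_config` (nested list).
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(j)
}

#' Build a run configuration from nested lists
#' @param x nested list with optional `synth`, `net`, `train`, `calib`,
#'   `eval` blocks.
#' @return object of class `run_config`.
#' @export
as_run_config <- function(x = list()) {
  cfg <- list(
    synth = do.call(synth_eye_config, x$synth %||% list()),
    net = do.call(net_config, x$net %||% list()),
    train = do.call(train_config, x$train %||% list()),
    calib = utils::modifyList(list(order = 2L, n_points = 12L, noise_sigma = 0),
                              x$calib %||% list()),
    eval = utils::modifyList(list(threshold_px = 5, px_per_mm = 2,
                                  viewing_distance_mm = 1000),
                             x$eval %||% list()),
    n_frames = x$n_frames %||% 50L,
    oracle = isTRUE(x$oracle)
  )
  class(cfg) <- "run_config"
  cfg
}
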