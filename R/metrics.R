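#' Fraction of detections within the pixel-error criterion
#'
#' A pupil detection counts as correct iff its center error is strictly
#' below the threshold (the standard criterion uses 5 px, so an error of
#' exactly 5 px is incorrect). `NA` entries (undefined comparisons, e.g.
#' closed-eye truth) are dropped from the denominator; `Inf` entries (failed
#' detections) count as incorrect.
#'
#' @param errors numeric vector of center errors in px.
#' @param threshold criterion in px, default 5.
#' @return fraction in `[0, 1]`.
#' @export
five_pixel_rate <- function(errors, threshold = 5) {
  errors <- errors[!is.na(errors)]
  if (length(errors) == 0) stop("no defined errors to rate", call. = FALSE)
  mean(errors < threshold)
}

#' Pooled detection precision
#'
#' `sum(TP) / (sum(TP) + sum(FP))` over consecutive sample batches. (The
#' source formula is often labelled "accuracy"; the quantity is the
#' confusion-matrix precision and the formula is kept exactly.)
#'
#' @param tp_counts,fp_counts nonnegative integer vectors.
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(tp_counts, fp_counts) {
  if (any(tp_counts < 0) || any(fp_counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  tot <- sum(tp_counts) + sum(fp_counts)
  if (tot == 0) stop("precision undefined: no positive predictions", call. = FALSE)
  sum(tp_counts) / tot
}

#' Root mean square error
#'
#' For scalar inputs the usual `sqrt(mean((b - a)^2))`; for 2-D points
#' (n x 2 matrices) the residual of each pair is its Euclidean distance.
#'
#' @param actual,estimated equal-length numeric vectors or n x 2 matrices.
#' @return RMSE `>= 0`, in the input units.
#' @export
rmse <- function(actual, estimated) {
  if (is.matrix(actual) || is.matrix(estimated)) {
    actual <- as.matrix(actual); estimated <- as.matrix(estimated)
    if (!all(dim(actual) == dim(estimated))) {
      stop("actual and estimated must have equal dimensions", call. = FALSE)
    }
    return(sqrt(mean(rowSums((actual - estimated)^2))))
  }
  if (length(actual) != length(estimated) || length(actual) < 1) {
    stop("actual and estimated must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((actual - estimated)^2))
}

#' Angular error between two gaze vectors
#'
#' `acos(a . b / (|a| |b|))`, returned in degrees; the cosine is clipped to
#' `[-1, 1]` against floating-point rounding. This is the standard accuracy
#' unit of eye trackers.
#'
#' @param a,b nonzero 3-vectors (or matrices of row vectors).
#' @return angle(s) in degrees.
#' @export
angular_error <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("gaze vectors must be nonzero", call. = FALSE)
  }
  cosang <- pmin(1, pmax(-1, rowSums(a * b) / (na * nb)))
  acos(cosang) * 180 / pi
}

#' Convert screen points to unit gaze vectors
#'
#' Assumes the eye sits on the screen-center normal at the configured
#' viewing distance; a screen point `(u, v)` in px then subtends the gaze
#' vector `((u - cu)/ppm, (v - cv)/ppm, D)` (normalized), with `ppm` pixels
#' per millimetre and `D` the viewing distance in mm. This is the geometry
#' needed to express screen-space errors in degrees.
#'
#' @param points n x 2 matrix (or length-2 vector) of screen points in px.
#' @param screen_geom list with `px_per_mm`, `viewing_distance_mm` and
#'   `center_px` `(cu, cv)`.
#' @return n x 3 matrix of unit gaze vectors.
#' @export
gaze_angles_from_screen <- function(points,
                                    screen_geom = list(px_per_mm = 2,
                                                       viewing_distance_mm = 1000,
                                                       center_px = c(320, 240))) {
  if (screen_geom$viewing_distance_mm <= 0) {
    stop("viewing distance must be positive", call. = FALSE)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  vx <- (points[, 1] - screen_geom$center_px[1]) / screen_geom$px_per_mm
  vy <- (points[, 2] - screen_geom$center_px[2]) / screen_geom$px_per_mm
  v <- cbind(vx, vy, screen_geom$viewing_distance_mm)
  v / sqrt(rowSums(v^2))
}

#' Gaze-point localization error
#'
#' Euclidean distance in px between a true target and an estimated gaze
#' point.
#'
#' @param truth,estimate length-2 vectors or n x 2 matrices.
#' @return distance(s) in px.
#' @export
localization_error <- function(truth, estimate) {
  if (is.null(dim(truth))) truth <- matrix(truth, ncol = 2)
  if (is.null(dim(estimate))) estimate <- matrix(estimate, ncol = 2)
  sqrt(rowSums((truth - estimate)^2))
}

#' N-fold cross-validation of the gaze mapping
#'
#' Points of a session are assigned to `k` folds by a seeded permutation;
#' each fold is held out once, the mapping is fitted on the remainder and
#' scored on the held-out points (2-D screen-space RMSE). Every training
#' fold must keep at least the model's `m` coefficient-count points.
#'
#' @param session a `gaze_session` (or [calibration_set()]).
#' @param k_folds number of folds, at least 2.
#' @param order polynomial order of the fitted mapping.
#' @param seed integer seed for the fold assignment.
#' @return list with `per_fold` (data.frame: fold, n_test, rmse),
#'   `mean_rmse`, `sd_rmse`.
#' @export
cross_validate <- function(session, k_folds = 5L, order = 2L, seed = 1L) {
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  pupil <- session$pupil; screen <- session$screen
  n <- nrow(pupil)
  m <- coefficient_count(order)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  if (any(tabulate(folds, k_folds) == 0)) {
    stop("more folds than points", call. = FALSE)
  }
  rows <- lapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    if (sum(tr) < m) {
      stop(sprintf("fold %d leaves %d training points, fewer than m = %d",
                   f, sum(tr), m), call. = FALSE)
    }
    model <- gaze_fit(calibration_set(pupil[tr, , drop = FALSE],
                                      screen[tr, , drop = FALSE]), order)
    pred <- gaze_predict(model, pupil[!tr, , drop = FALSE])
    data.frame(fold = f, n_test = sum(!tr),
               rmse = rmse(screen[!tr, , drop = FALSE], pred))
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, mean_rmse = mean(per_fold$rmse),
       sd_rmse = sd(per_fold$rmse))
}
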