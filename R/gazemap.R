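#' Polynomial gaze-mapping model
#'
#' The calibration maps pupil-center vectors `(x, y)` in eye-camera pixels to
#' screen/scene coordinates `(u, v)` through a pair of bivariate polynomials
#' of total degree `n`:
#' \deqn{u = A_0 + A_1 x + A_2 y + A_3 x^2 + A_4 x y + A_5 y^2}
#' (and likewise `v` with coefficients `B`). The monomial order is fixed as
#' `1, x, y, x^2, xy, y^2, ...` so the coefficient indices match the usual
#' second-order calibration notation. The coefficient count is
#' `m = 1 + sum_{i=1..n} (1 + i)`, i.e. 3 for a first-order and 6 for a
#' second-order model — hence six calibration points.
#'
#' @param A,B numeric coefficient vectors of length `coefficient_count(order)`.
#' @param order polynomial order, a positive integer.
#' @return an object of class `mapping_model`.
#' @export
mapping_model <- function(A, B, order = 2L) {
  order <- as.integer(order)
  m <- coefficient_count(order)
  if (length(A) != m || length(B) != m) {
    stop(sprintf("order-%d model needs coefficient vectors of length %d", order, m),
         call. = FALSE)
  }
  if (!all(is.finite(A)) || !all(is.finite(B))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(order = order, A = as.numeric(A), B = as.numeric(B), m = m),
            class = "mapping_model")
}

#' Number of polynomial coefficients for a mapping of given order
#'
#' Closed form `m = 1 + sum_{i=1..n}(1 + i)`, which equals the number of
#' bivariate monomials of total degree at most `n`: 3 for `n = 1`, 6 for
#' `n = 2`, 10 for `n = 3`.
#'
#' @param n polynomial order, integer >= 1.
#' @return integer coefficient count `m`.
#' @export
coefficient_count <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("polynomial order must be an integer >= 1", call. = FALSE)
  }
  1L + sum(1L + seq_len(n))
}

# design-matrix rows [1, x, y, x^2, xy, y^2, x^3, ...] for total degree <= n,
# degree-major, x-power descending within a degree (matches A0..A5 indexing)
design_matrix <- function(xy, n) {
  x <- xy[, 1]; y <- xy[, 2]
  cols <- list(rep(1, length(x)))
  for (d in seq_len(n)) {
    for (px in d:0) {
      cols[[length(cols) + 1L]] <- x^px * y^(d - px)
    }
  }
  M <- do.call(cbind, cols)
  # reorder within each degree so x-descending becomes the conventional
  # [x, y], [x^2, xy, y^2] ordering (already is: px descending)
  M
}

#' Assemble a calibration set from pupil/target pairs
#'
#' @param pupil n x 2 matrix of pupil vectors `(x, y)`.
#' @param screen n x 2 matrix of screen targets `(u, v)`.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(pupil, screen) {
  pupil <- as.matrix(pupil); screen <- as.matrix(screen)
  if (nrow(pupil) != nrow(screen) || ncol(pupil) != 2 || ncol(screen) != 2) {
    stop("pupil and screen must be n x 2 matrices with equal n", call. = FALSE)
  }
  structure(list(pupil = pupil, screen = screen), class = "calibration_set")
}

#' Fit the polynomial gaze mapping to calibration data
#'
#' With exactly `m` points the coefficients solve the square system
#' `A = M^{-1} u`, `B = M^{-1} v`; with more points the system is solved in
#' the least-squares sense (pseudoinverse), which is the mean-square-deviation
#' criterion the calibration minimizes. Rank-deficient designs (e.g. collinear
#' calibration points for a second-order fit) are rejected.
#'
#' @param calib a [calibration_set()] or `gaze_session`.
#' @param order polynomial order (1 or 2 are the standard choices).
#' @return a [mapping_model()].
#' @export
gaze_fit <- function(calib, order = 2L) {
  if (inherits(calib, "gaze_session")) {
    calib <- calibration_set(calib$pupil, calib$screen)
  }
  stopifnot(inherits(calib, "calibration_set"))
  m <- coefficient_count(order)
  npt <- nrow(calib$pupil)
  if (npt < m) {
    stop(sprintf("need at least m = %d calibration points for order %d, got %d",
                 m, order, npt), call. = FALSE)
  }
  M <- design_matrix(calib$pupil, order)
  qrM <- qr(M)
  if (qrM$rank < m) {
    stop(sprintf("design matrix is rank deficient (rank %d < m = %d): calibration points are degenerate (e.g. collinear)",
                 qrM$rank, m), call. = FALSE)
  }
  A <- qr.coef(qrM, calib$screen[, 1])
  B <- qr.coef(qrM, calib$screen[, 2])
  mapping_model(A = A, B = B, order = order)
}

#' Evaluate the gaze mapping at pupil vectors
#'
#' @param model a [mapping_model()].
#' @param pupil a length-2 vector `(x, y)` or an n x 2 matrix.
#' @return an n x 2 matrix of screen coordinates `(u, v)` (a 1 x 2 matrix for
#'   a single vector input).
#' @export
gaze_predict <- function(model, pupil) {
  stopifnot(inherits(model, "mapping_model"))
  if (is.null(dim(pupil))) pupil <- matrix(pupil, ncol = 2)
  M <- design_matrix(pupil, model$order)
  out <- cbind(M %*% model$A, M %*% model$B)
  colnames(out) <- c("u", "v")
  out
}

#' Standard six-point calibration target layout
#'
#' Four inset corner targets, the display center, and a mid-top target. Six
#' points are exactly enough to determine the second-order mapping, but only
#' in general position: a fully symmetric layout (e.g. corners plus two
#' points on the vertical midline) lies on a degenerate conic and makes the
#' quadratic design matrix rank deficient, so the layout deliberately breaks
#' that symmetry.
#'
#' @param display_bounds `(umin, umax, vmin, vmax)` in px.
#' @param inset fractional inset from the display border.
#' @return a 6 x 2 matrix of `(u, v)` targets.
#' @export
calibration_targets <- function(display_bounds = c(0, 640, 0, 480),
                                inset = 0.1) {
  du <- diff(display_bounds[1:2]); dv <- diff(display_bounds[3:4])
  u0 <- display_bounds[1] + inset * du; u1 <- display_bounds[2] - inset * du
  v0 <- display_bounds[3] + inset * dv; v1 <- display_bounds[4] - inset * dv
  um <- (u0 + u1) / 2; vm <- (v0 + v1) / 2
  rbind(c(u0, v0), c(u1, v0), c(u0, v1), c(u1, v1), c(um, vm), c(um, v0))
}

#' @export
print.mapping_model <- function(x, ...) {
  cat(sprintf("<mapping_model> order %d (m = %d)\n", x$order, x$m))
  cat("  A:", paste(signif(x$A, 4), collapse = " "), "\n")
  cat("  B:", paste(signif(x$B, 4), collapse = " "), "\n")
  invisible(x)
}
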