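#' Extract pupil center, ellipse and diameter from a probability map
#'
#' The map is thresholded, the largest 8-connected component kept, and the
#' pupil measured from that component's probability-weighted image moments:
#' the center is the weighted centroid and the ellipse follows from the
#' second-order central moments (for a solid ellipse the principal second
#' moments are `a^2/4` and `b^2/4`). The moment estimator needs no iterative
#' boundary fit and is robust on small masks. Degenerate inputs (empty or
#' fewer than 10 pixels above threshold) yield `valid = FALSE`, never an
#' error.
#'
#' @param prob_map `H x W` matrix of pupil probabilities in `[0, 1]`.
#' @param threshold probability cutoff, default 0.5.
#' @return a `pupil_state`: list with `center` `(cx, cy)` in 0-based px,
#'   `semi_axes` `(a, b)` with `a >= b`, `orientation` in `[0, pi)`,
#'   `diameter` (`= 2a`), `closed`, `valid`, `n_pixels`.
#' @export
extract_pupil <- function(prob_map, threshold = 0.5) {
  stopifnot(is.matrix(prob_map))
  mask <- prob_map >= threshold
  invalid <- structure(list(center = c(NA_real_, NA_real_),
                            semi_axes = c(NA_real_, NA_real_),
                            orientation = NA_real_, diameter = NA_real_,
                            closed = FALSE, valid = FALSE, n_pixels = 0L),
                       class = "pupil_state")
  if (!any(mask)) return(invalid)
  lab <- cpp_label_components(mask)
  tab <- tabulate(lab[lab > 0])
  comp <- which.max(tab)
  sel <- lab == comp
  n_px <- sum(sel)
  if (n_px < 10L) { invalid$n_pixels <- n_px; return(invalid) }
  idx <- which(sel)
  h <- nrow(prob_map)
  ys <- (idx - 1) %% h          # 0-based row = y
  xs <- (idx - 1) %/% h         # 0-based col = x
  w <- prob_map[idx]
  sw <- sum(w)
  cx <- sum(w * xs) / sw
  cy <- sum(w * ys) / sw
  mxx <- sum(w * (xs - cx)^2) / sw
  myy <- sum(w * (ys - cy)^2) / sw
  mxy <- sum(w * (xs - cx) * (ys - cy)) / sw
  cov <- matrix(c(mxx, mxy, mxy, myy), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(max(eg$values[1], 1e-12))
  b <- 2 * sqrt(max(eg$values[2], 1e-12))
  vmax <- eg$vectors[, 1]
  theta <- atan2(vmax[2], vmax[1]) %% pi
  structure(list(center = c(cx, cy), semi_axes = c(a, b),
                 orientation = theta, diameter = 2 * a, closed = FALSE,
                 valid = TRUE, n_pixels = n_px),
            class = "pupil_state")
}

#' Pupil-center pixel error
#'
#' Euclidean distance between a detected pupil center and the annotated
#' ground-truth center — the quantity behind the 5-pixel correctness
#' criterion. Comparing against a closed-eye annotation is undefined and
#' returns `NA` (such frames are excluded from rate denominators).
#'
#' @param state a `pupil_state` from [extract_pupil()].
#' @param truth a `pupil_annotation` (or a `pupil_state`).
#' @return distance in px, or `NA` when undefined.
#' @export
pixel_error <- function(state, truth) {
  if (isTRUE(truth$closed)) return(NA_real_)
  if (!is.null(state$valid) && !isTRUE(state$valid)) return(NA_real_)
  sqrt(sum((state$center - truth$center)^2))
}

#' @export
print.pupil_state <- function(x, ...) {
  if (!x$valid) {
    cat("<pupil_state> invalid (", x$n_pixels, "px )\n")
  } else {
    cat(sprintf("<pupil_state> center (%.2f, %.2f)  axes (%.2f, %.2f)  theta %.3f rad  diameter %.2f px\n",
                x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
                x$orientation, x$diameter))
  }
  invisible(x)
}
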