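#' Map an upsampled target location to its source location
#'
#' CARAFE upsampling associates every target location `q = (u, v)` in the
#' `r`-times enlarged feature map with the source location
#' `p = (s, t) = (floor(u/r), floor(v/r))` in the input map. Locations are
#' 0-based integers.
#'
#' @param q integer vector `(u, v)`, 0-based.
#' @param r integer upsampling ratio >= 1.
#' @return integer vector `(s, t)`.
#' @export
carafe_source <- function(q, r) {
  if (any(q < 0) || r < 1) stop("q must be nonnegative and r >= 1", call. = FALSE)
  as.integer(floor(q / r))
}

#' Predict content-aware reassembly kernels
#'
#' A learned predictor (a single convolution producing `r^2 m^2` channels,
#' pixel-shuffled to the upsampled grid) turns the `m x m` neighborhood of
#' each source location into one `m x m` reassembly kernel per target
#' location. Kernels are normalized with a softmax over their `m^2` entries,
#' so each is nonnegative and sums to 1; a zero-initialized predictor yields
#' uniform kernels of value `1/m^2`.
#'
#' @param features `H x W x C` array (single feature map; a plain matrix is
#'   treated as `C = 1`).
#' @param predictor list with conv weights `W` (`k x k x C x (r^2 m^2)`) and
#'   bias `b`; see [carafe_predictor_init()].
#' @param m odd kernel size >= 3.
#' @param r upsampling ratio.
#' @return array of kernels, `m^2 x rH x rW`, each column-slice summing to 1.
#' @export
carafe_predict_kernels <- function(features, predictor, m, r = 2L) {
  if (m %% 2 == 0 || m < 3) stop("kernel size m must be odd and >= 3", call. = FALSE)
  x <- as_feature_batch(features)
  P <- cpp_conv2d_fwd(x, predictor$W, predictor$b,
                      as.integer((dim(predictor$W)[1] - 1) / 2))
  K <- cpp_carafe_kernels(P, as.integer(m), as.integer(r))
  array(K, dim(K)[1:3])
}

#' Reassemble features with predicted kernels (CARAFE upsampling)
#'
#' Each output value is the weighted sum of the `m x m` source neighborhood
#' of `carafe_source(q, r)` under the kernel for `q`; the weighting is shared
#' across channels and neighborhoods are zero-padded at the border. A delta
#' kernel therefore reproduces nearest-neighbor upsampling and uniform
#' kernels average the neighborhood.
#'
#' @param features `H x W x C` array or `H x W` matrix.
#' @param kernels `m^2 x rH x rW` array of nonnegative kernels.
#' @param m odd kernel size.
#' @param r upsampling ratio.
#' @return upsampled `rH x rW x C` array (matrix input gives a matrix back).
#' @export
carafe_reassemble <- function(features, kernels, m, r = 2L) {
  x <- as_feature_batch(features)
  d <- dim(x)
  if (!all(dim(kernels) == c(m * m, d[1] * r, d[2] * r))) {
    stop(sprintf("kernels must be %d x %d x %d for this input",
                 m * m, d[1] * r, d[2] * r), call. = FALSE)
  }
  K <- array(kernels, c(dim(kernels), 1L))
  out <- cpp_carafe_apply(x, K, as.integer(m), as.integer(r))
  if (is.matrix(features)) matrix(out, d[1] * r, d[2] * r)
  else array(out, dim(out)[1:3])
}

#' Initialize a CARAFE kernel-predictor convolution
#'
#' @param channels input channel count.
#' @param m odd kernel size.
#' @param r upsampling ratio.
#' @param k spatial size of the predictor convolution.
#' @param zero if `TRUE`, zero-initialize (gives uniform kernels).
#' @return list with `W` and `b`.
#' @export
carafe_predictor_init <- function(channels, m, r = 2L, k = 3L, zero = FALSE) {
  cout <- r * r * m * m
  W <- if (zero) array(0, c(k, k, channels, cout)) else he_init(k, channels, cout)
  list(W = W, b = numeric(cout))
}

as_feature_batch <- function(features) {
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  if (length(dim(features)) != 3) stop("features must be H x W x C", call. = FALSE)
  array(features, c(dim(features), 1L))
}
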