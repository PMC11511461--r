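#' Evaluate an expression under a private, restorable RNG state
#'
#' All seeded generators in the package route randomness through this helper
#' so that the caller's RNG stream is never disturbed and identical seeds give
#' identical output.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clip01 <- function(x) {
  # keep dim attributes (pmax(0, x) would take them from the scalar)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Logistic-regression style probability clipping
#' @keywords internal
clip_prob <- function(p, delta = 1e-7) pmin(1 - delta, pmax(delta, p))

# derive a stream-specific 31-bit sub-seed from a master seed; arithmetic in
# doubles (exact below 2^53) so nested derivations cannot overflow
subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
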