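#' Numerically stable logistic sigmoid
#'
#' Elementwise `1 / (1 + exp(-u))`, the activation used by both the encoder
#' and decoder layers. Delegates to [stats::plogis()], which is stable over
#' the whole double range.
#'
#' @param u numeric scalar, vector or matrix; must be finite.
#' @return object of the same shape with values in (0, 1).
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(700)  # ~1, no overflow
#' @export
sigmoid <- function(u) {
  if (any(!is.finite(u))) stop("sigmoid: input must be finite")
  out <- stats::plogis(u)
  if (is.matrix(u)) dim(out) <- dim(u)
  out
}

# run expr with a fixed RNG seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# one-hot encode 0-based labels into an N x k indicator matrix
oneHot <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= k)) {
    stop(sprintf("labels must lie in 0..%d", k - 1L))
  }
  Y <- matrix(0, length(labels), k)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# classification accuracy helper shared by the benchmark module
checkMatrix <- function(X, what = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(what, " must be a numeric matrix")
  X
}
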