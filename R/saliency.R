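#' Gradient of one softmax probability with respect to its input features
#'
#' For class j, `dP_j/df = P_j * (theta_j - sum_l P_l theta_l)`, the
#' numerically stable form of the softmax Jacobian row (algebraically equal
#' to the quotient-rule expression
#' `sum_l (theta_j - theta_l) e^((theta_j + theta_l)' f) / (sum_l e^(theta_l' f))^2`).
#' Bias handling is the caller's concern: `theta` here acts on the features
#' as given.
#'
#' @param theta k x d softmax weight matrix.
#' @param features length-d feature vector.
#' @param j 0-based class index.
#' @return length-d gradient vector.
#' @examples
#' # two classes, scalar feature: reduces to the logistic derivative
#' softmaxInputJacobian(matrix(c(1, 0), 2, 1), 0, j = 0L)  # 0.25
#' @export
softmaxInputJacobian <- function(theta, features, j) {
  features <- as.numeric(features)
  if (length(features) != ncol(theta)) {
    stop(sprintf("feature length %d does not match theta's %d",
                 length(features), ncol(theta)))
  }
  j <- as.integer(j)
  if (j < 0L || j >= nrow(theta)) {
    stop(sprintf("class index %d out of range 0..%d", j, nrow(theta) - 1L))
  }
  p <- drop(softmaxProbs(theta, matrix(features, 1)))
  drop(p[j + 1L] * (theta[j + 1L, ] - crossprod(p, theta)))
}

#' Guided-backward saliency of a stacked model
#'
#' Backpropagates the supervised loss through the softmax and every sigmoid
#' encoder layer down to the input spectrum: per sample, the gradient of
#' `-log P(true class)` with respect to the input is computed by chaining
#' the loss-to-probability derivative, the softmax Jacobian, and the
#' encoder-layer Jacobians. Per-sample gradients are then pooled into one
#' per-wavenumber importance curve. When the model stores a scaling record
#' the chain continues through the affine scaling, so the saliency refers
#' to raw absorbance units.
#'
#' True-class probabilities are clamped at 1e-12 where they enter the loss;
#' the gradient itself is computed in the clamp-free stable form
#' `(P - onehot) theta`.
#'
#' @param model a trained [SSAEModel-class].
#' @param x a [SpectralSet-class] (labels taken from it) or a samples x
#'   variables matrix already on the model's input scale.
#' @param y labels, required when `x` is a matrix.
#' @param aggregation pooling of per-sample gradients: `"classMeanMax"`
#'   (default: per-class signed mean, then the value of largest magnitude
#'   across classes), `"mean"` (signed mean over all samples; class effects
#'   of opposite sign cancel, which flattens the saliency of genuinely
#'   informative bands), or `"meanAbs"` (mean absolute value, unsigned).
#' @return a [GuidedSaliency-class].
#' @export
guidedBackward <- function(model, x, y = NULL,
                           aggregation = c("classMeanMax", "mean",
                                           "meanAbs")) {
  aggregation <- match.arg(aggregation)
  wn <- numeric(0)
  scaleJac <- NULL
  if (methods::is(x, "SpectralSet")) {
    y <- classLabels(x)
    wn <- wavenumbers(x)
    X <- spectra(x)
    if (length(model@scaling)) {
      rec <- model@scaling
      span <- rec$max - rec$min
      scaleJac <- ifelse(rec$constant, 0,
                         (rec$hi - rec$lo) / ifelse(span == 0, 1, span))
      X <- applyScaling(X, rec)
    }
  } else {
    X <- checkMatrix(x)
    if (is.null(y)) stop("labels y are required with a matrix input")
  }
  if (all(model@theta == 0)) {
    stop("model looks untrained (all softmax weights are zero); ",
         "fine-tune before computing saliency")
  }
  G <- perSampleInputGradients(model, X, as.integer(y))
  if (!is.null(scaleJac)) G <- sweep(G, 2, scaleJac, "*")
  raw <- switch(aggregation,
    mean = colMeans(G),
    meanAbs = colMeans(abs(G)),
    classMeanMax = {
      yy <- as.integer(y)
      M <- do.call(rbind, lapply(sort(unique(yy)), function(cl)
        colMeans(G[yy == cl, , drop = FALSE])))
      M[cbind(max.col(t(abs(M)), ties.method = "first"), seq_len(ncol(M)))]
    })
  mx <- max(abs(raw))
  methods::new("GuidedSaliency", raw = raw,
               normalized = if (mx > 0) raw / mx else raw,
               aggregation = aggregation, nSamples = nrow(G),
               wavenumbers = as.numeric(wn))
}

# gradient of the per-sample loss -log P(y_i | x_i) w.r.t. each input row
perSampleInputGradients <- function(model, X, y) {
  k <- nrow(model@theta)
  fwd <- ssaeForward(model@encoders, X)
  P <- softmaxProbs(model@theta, addBias(fwd$features))
  nf <- ncol(fwd$features)
  dH <- (P - oneHot(y, k)) %*% model@theta[, seq_len(nf), drop = FALSE]
  for (l in rev(seq_along(model@encoders))) {
    H <- fwd$hidden[[l]]
    dH <- (dH * H * (1 - H)) %*% model@encoders[[l]]$W
  }
  dH
}

#' Threshold a saliency curve into selected wavenumbers
#'
#' Keeps the strong peaks and valleys of the normalized saliency: index p
#' is selected when `|normalized[p]| > threshold` and p is a local extremum
#' of `|normalized|` (at least as large as both neighbours; plateau ties
#' resolve to the leftmost index). The default threshold 0.5 operates on
#' the `[-1, 1]` normalized scale.
#'
#' @param saliency a [GuidedSaliency-class].
#' @param threshold in (0, 1].
#' @return a [SelectionResult-class] sorted along the (descending) axis.
#' @examples
#' s <- methods::new("GuidedSaliency",
#'                   raw = c(0.2, 0.9, 0.3, -0.7, -0.2),
#'                   normalized = c(0.2, 0.9, 0.3, -0.7, -0.2) / 0.9,
#'                   aggregation = "mean", nSamples = 1L,
#'                   wavenumbers = c(5, 4, 3, 2, 1))
#' selectedIndices(selectWavenumbers(s, 0.5))  # 2 and 4
#' @export
selectWavenumbers <- function(saliency, threshold = 0.5) {
  stopifnot(methods::is(saliency, "GuidedSaliency"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  a <- abs(saliency@normalized)
  P <- length(a)
  left <- c(-Inf, a[-P])
  right <- c(a[-1], -Inf)
  keep <- a > threshold & a >= left & a >= right
  # plateau: drop members whose left neighbour is an equal kept extremum
  plateau <- which(keep & a == left & c(FALSE, keep[-P]))
  keep[plateau] <- FALSE
  idx <- which(keep)
  methods::new("SelectionResult", method = "ssae-gb",
               indices = as.integer(idx),
               wavenumbers = if (length(saliency@wavenumbers))
                 saliency@wavenumbers[idx] else numeric(length(idx)),
               threshold = threshold, note = "")
}

#' Selected fraction of the spectrum
#'
#' `100 * nSelected / nTotal`, reported at three decimals: 38 of 7157
#' variables is 0.531 percent of the full spectrum, 300 of 7157 is 4.192
#' percent.
#'
#' @param nSelected,nTotal selected and total variable counts.
#' @return percentage rounded to 3 decimals.
#' @export
selectionFraction <- function(nSelected, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nSelected < 0 || nSelected > nTotal) {
    stop("nSelected must lie in 0..nTotal")
  }
  round(100 * nSelected / nTotal, 3)
}
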