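#' Greedy layerwise pretraining of an encoder stack
#'
#' Trains a sparse auto-encoder on the (scaled) input, discards its decoder,
#' feeds the hidden representation to the next auto-encoder, and so on. The
#' hidden representation of each layer is the input of the next; only the
#' encoder halves survive into the stacked model.
#'
#' @param X samples x input matrix, entries in \[0, 1\].
#' @param layerSizes integer vector of hidden widths, e.g. `c(2048, 13)` for
#'   the two-hidden-layer configuration used for full-resolution spectra, or
#'   something like `c(64, 13)` at desk scale.
#' @param rho,beta sparsity target and weight passed to every layer.
#' @param opts a [trainOptions()] list; the seed is offset per layer.
#' @return list of encoder layers, each `list(W, b)`.
#' @export
stackPretrain <- function(X, layerSizes, rho = 0.05, beta = 3,
                          opts = trainOptions()) {
  X <- checkScaled(X)
  if (!length(layerSizes)) stop("layerSizes must be non-empty")
  encoders <- vector("list", length(layerSizes))
  H <- X
  for (i in seq_along(layerSizes)) {
    layerOpts <- opts
    layerOpts$seed <- opts$seed + (i - 1L) * 1000L
    fit <- tryCatch(
      trainSAE(H, layerSizes[i], rho = rho, beta = beta, opts = layerOpts),
      error = function(e) {
        stop(sprintf("pretraining failed in layer %d: %s", i,
                     conditionMessage(e)))
      })
    encoders[[i]] <- list(W = fit$params@W1, b = fit$params@b1)
    H <- saeEncode(fit$params, H)
  }
  encoders
}

# forward through the encoder stack; returns list of activations per layer
# (activations[[0+1]] = X is not stored; inputs[[l]] is the input to layer l)
ssaeForward <- function(encoders, X) {
  inputs <- vector("list", length(encoders))
  hidden <- vector("list", length(encoders))
  H <- X
  for (l in seq_along(encoders)) {
    inputs[[l]] <- H
    pre <- sweep(tcrossprod(H, encoders[[l]]$W), 2, encoders[[l]]$b, "+")
    H <- sigmoid(pre)
    hidden[[l]] <- H
  }
  list(inputs = inputs, hidden = hidden, features = H)
}

#' Softmax class probabilities
#'
#' Row i, class j equals `exp(theta_j' f_i) / sum_l exp(theta_l' f_i)`,
#' computed with row-max subtraction for numerical stability. `features`
#' are used as given; the model functions append the constant-1 bias
#' feature before calling this.
#'
#' @param theta k x d weight matrix.
#' @param features N x d feature matrix.
#' @return N x k matrix of probabilities; each row sums to 1.
#' @export
softmaxProbs <- function(theta, features) {
  features <- checkMatrix(features)
  if (ncol(features) != ncol(theta)) {
    stop(sprintf("feature dimension %d does not match theta's %d",
                 ncol(features), ncol(theta)))
  }
  S <- tcrossprod(features, theta)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

addBias <- function(features) cbind(features, 1)

#' Construct an untrained stacked model from pretrained encoders
#'
#' @param encoders encoder list from [stackPretrain()].
#' @param nClasses number of classes k.
#' @param lambda weight decay on the softmax parameters (default 1e-4).
#' @param scaling optional scaling record stored for prediction time.
#' @param inputDim input dimension; required only for the degenerate
#'   zero-encoder model (softmax acting directly on the spectrum), which is
#'   provided for comparing saliency with and without the encoder chain.
#' @return an [SSAEModel-class] with zero-initialised softmax weights (the
#'   softmax problem is convex in `theta` given fixed features, so zero
#'   initialisation is canonical).
#' @export
newSSAEModel <- function(encoders, nClasses, lambda = 1e-4,
                         scaling = list(), inputDim = NULL) {
  d <- if (length(encoders)) nrow(encoders[[length(encoders)]]$W)
       else if (!is.null(inputDim)) as.integer(inputDim)
       else stop("need encoder layers or an explicit inputDim")
  methods::new("SSAEModel", encoders = encoders,
               theta = matrix(0, nClasses, d + 1L),
               lambda = lambda,
               layerSizes = vapply(encoders, function(e) nrow(e$W), 1L),
               scaling = scaling)
}

#' Supervised softmax loss of the full stacked model
#'
#' Mean negative log-probability of the true class over the samples plus
#' the weight-decay term `lambda/2 * ||theta||^2`. Only the softmax
#' parameters are penalised; encoder weights carry no decay.
#'
#' @param model an [SSAEModel-class].
#' @param X samples x input matrix on the scale the encoders were trained on.
#' @param y integer labels in `0..k-1`.
#' @return scalar loss.
#' @export
supervisedLoss <- function(model, X, y) {
  X <- checkMatrix(X)
  k <- nrow(model@theta)
  y <- as.integer(y)
  if (any(y < 0L | y >= k)) stop(sprintf("labels must lie in 0..%d", k - 1L))
  F <- ssaeForward(model@encoders, X)$features
  P <- softmaxProbs(model@theta, addBias(F))
  pTrue <- pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)
  -mean(log(pTrue)) + model@lambda / 2 * sum(model@theta^2)
}

# gradient of supervisedLoss w.r.t. theta and every encoder (W, b)
supervisedGradient <- function(model, X, y) {
  X <- checkMatrix(X)
  k <- nrow(model@theta)
  N <- nrow(X)
  fwd <- ssaeForward(model@encoders, X)
  Faug <- addBias(fwd$features)
  P <- softmaxProbs(model@theta, Faug)
  D <- (P - oneHot(y, k)) / N
  gTheta <- crossprod(D, Faug) + model@lambda * model@theta
  nf <- ncol(fwd$features)
  dH <- D %*% model@theta[, seq_len(nf), drop = FALSE]
  gEnc <- vector("list", length(model@encoders))
  for (l in rev(seq_along(model@encoders))) {
    H <- fwd$hidden[[l]]
    dA <- dH * H * (1 - H)
    gEnc[[l]] <- list(W = crossprod(dA, fwd$inputs[[l]]), b = colSums(dA))
    dH <- dA %*% model@encoders[[l]]$W
  }
  list(theta = gTheta, encoders = gEnc, probs = P, loss =
         -mean(log(pmax(P[cbind(seq_len(N), y + 1L)], 1e-12))) +
         model@lambda / 2 * sum(model@theta^2))
}

#' Supervised fine-tuning of the whole stacked network
#'
#' Gradient descent on the softmax loss updating both the softmax
#' parameters and every encoder layer by backpropagation (the entire
#' network is fine-tuned; the sparsity penalty is not applied at this
#' stage). Deterministic given the model and options.
#'
#' @param model an [SSAEModel-class] with pretrained encoders.
#' @param X samples x input matrix (same scaling as pretraining).
#' @param y integer labels in `0..k-1`.
#' @param opts a [trainOptions()] list (full-batch descent).
#' @return list with `model` (fine-tuned) and `history` (per-epoch loss).
#' @export
fineTune <- function(model, X, y, opts = trainOptions(epochs = 1000L,
                                                      learningRate = 1)) {
  X <- checkMatrix(X)
  history <- numeric(opts$epochs)
  for (epoch in seq_len(opts$epochs)) {
    g <- supervisedGradient(model, X, y)
    if (!is.finite(g$loss)) {
      stop(sprintf("fine-tuning diverged at epoch %d", epoch))
    }
    history[epoch] <- g$loss
    model@theta <- model@theta - opts$learningRate * g$theta
    for (l in seq_along(model@encoders)) {
      model@encoders[[l]]$W <- model@encoders[[l]]$W -
        opts$learningRate * g$encoders[[l]]$W
      model@encoders[[l]]$b <- model@encoders[[l]]$b -
        opts$learningRate * g$encoders[[l]]$b
    }
  }
  list(model = model, history = history)
}

#' Predict class labels
#'
#' Argmax over the softmax probabilities; exact ties resolve to the
#' smallest class index (deterministic).
#'
#' @param model a trained [SSAEModel-class].
#' @param X samples x input matrix, or a [SpectralSet-class] (raw
#'   absorbance; the model's stored scaling record is applied).
#' @return integer labels in `0..k-1`.
#' @export
predictClasses <- function(model, X) {
  if (methods::is(X, "SpectralSet")) {
    X <- spectra(X)
    if (length(model@scaling)) X <- applyScaling(X, model@scaling)
  }
  X <- checkMatrix(X)
  F <- ssaeForward(model@encoders, X)$features
  P <- softmaxProbs(model@theta, addBias(F))
  max.col(P, ties.method = "first") - 1L
}

#' Pretrain and fine-tune an SSAE classifier on a SpectralSet
#'
#' Convenience wrapper running the full pipeline: scale the absorbance into
#' the sigmoid's range, greedy layerwise pretraining, then supervised
#' fine-tuning of the entire network. The scaling record is stored in the
#' model so [predictClasses()] and [guidedBackward()] accept raw spectra.
#'
#' @param x a [SpectralSet-class], or a raw samples x wavenumbers matrix if
#'   `y` is given.
#' @param y labels (ignored when `x` is a SpectralSet).
#' @param layerSizes hidden widths (default `c(64, 13)`; use
#'   `c(2048, 13)` to mirror the full-resolution configuration).
#' @param rho,beta sparsity target and weight for pretraining.
#' @param lambda softmax weight decay.
#' @param pretrainOpts,finetuneOpts [trainOptions()] for the two phases.
#' @param scaleRange `c(lo, hi)` for [scaleToUnitInterval()].
#' @return list with `model`, `pretrainHistory` (last layer) and
#'   `finetuneHistory`.
#' @export
trainSSAE <- function(x, y = NULL, layerSizes = c(64L, 13L),
                      rho = 0.05, beta = 3, lambda = 1e-4,
                      pretrainOpts = trainOptions(epochs = 150L,
                                                  learningRate = 0.1),
                      finetuneOpts = trainOptions(epochs = 1500L,
                                                  learningRate = 1),
                      scaleRange = c(0.05, 0.95)) {
  if (methods::is(x, "SpectralSet")) {
    y <- classLabels(x)
    k <- length(classNames(x))
    x <- spectra(x)
  } else {
    y <- as.integer(y)
    k <- max(y) + 1L
  }
  sc <- scaleToUnitInterval(x, scaleRange[1], scaleRange[2])
  encoders <- stackPretrain(sc$scaled, layerSizes, rho = rho, beta = beta,
                            opts = pretrainOpts)
  model <- newSSAEModel(encoders, nClasses = k, lambda = lambda,
                        scaling = sc$record)
  ft <- fineTune(model, sc$scaled, y, opts = finetuneOpts)
  list(model = ft$model, finetuneHistory = ft$history)
}
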