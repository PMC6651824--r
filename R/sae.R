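#' Training options for gradient-descent optimisation
#'
#' @param epochs number of passes (full-batch updates by default).
#' @param learningRate step size of plain gradient descent.
#' @param batchSize mini-batch size, or `NULL` (default) for full batch.
#'   Full batch is the reference mode: the mean hidden activation entering
#'   the sparsity penalty is then exactly the average over all training
#'   samples. Mini-batch mode approximates it with an exponential moving
#'   average (decay 0.99) and is flagged as an approximation.
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @param initScale multiplier on the uniform Glorot initialisation radius
#'   `sqrt(6 / (fanIn + fanOut))`.
#' @return list of class `"TrainOptions"`.
#' @export
trainOptions <- function(epochs = 200L, learningRate = 0.1, batchSize = NULL,
                         seed = 1L, initScale = 1) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be > 0")
  if (initScale <= 0) stop("initScale must be > 0")
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = if (is.null(batchSize)) NULL
                             else as.integer(batchSize),
                 seed = as.integer(seed), initScale = initScale),
            class = "TrainOptions")
}

#' Encode / decode through a sparse auto-encoder layer
#'
#' `saeEncode()` computes the hidden representation
#' `H = sigmoid(X W1' + b1)`; `saeDecode()` reconstructs
#' `Z = sigmoid(H W2' + b2)`.
#'
#' @param params an [SAEParams-class].
#' @param X samples x input matrix (for `saeEncode`).
#' @param H samples x hidden matrix (for `saeDecode`).
#' @return matrix with entries in (0, 1).
#' @export
saeEncode <- function(params, X) {
  X <- checkMatrix(X)
  if (ncol(X) != ncol(params@W1)) {
    stop(sprintf("input has %d variables but encoder expects %d",
                 ncol(X), ncol(params@W1)))
  }
  sigmoid(sweep(tcrossprod(X, params@W1), 2, params@b1, "+"))
}

#' @rdname saeEncode
#' @export
saeDecode <- function(params, H) {
  H <- checkMatrix(H)
  if (ncol(H) != ncol(params@W2)) {
    stop(sprintf("hidden input has %d units but decoder expects %d",
                 ncol(H), ncol(params@W2)))
  }
  sigmoid(sweep(tcrossprod(H, params@W2), 2, params@b2, "+"))
}

#' Bernoulli Kullback-Leibler sparsity divergence
#'
#' `sum_j rho*log(rho/rhoHat_j) + (1-rho)*log((1-rho)/(1-rhoHat_j))`
#' (natural logarithm), the penalty pulling mean hidden activations toward
#' the sparsity target. Non-negative, zero iff every `rhoHat_j == rho`.
#' Activations are clamped away from 0/1 by `1e-10` before taking logs.
#'
#' @param rho target sparsity, in (0, 1).
#' @param rhoHat vector of mean hidden activations.
#' @return scalar divergence.
#' @examples
#' klDivergence(0.05, c(0.05, 0.05))  # 0
#' @export
klDivergence <- function(rho, rhoHat) {
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0 || rho >= 1) {
    stop("rho must be a single value in (0, 1)")
  }
  eps <- 1e-10
  r <- pmin(pmax(rhoHat, eps), 1 - eps)
  sum(rho * log(rho / r) + (1 - rho) * log((1 - rho) / (1 - r)))
}

#' Sparse auto-encoder loss
#'
#' Reconstruction error plus sparsity penalty:
#' `0.5 * sum_i ||z_i - x_i||^2 + beta * sum_j KL(rho || rhoHat_j)` where
#' `rhoHat_j` is the mean activation of hidden unit j over all samples.
#'
#' @param params an [SAEParams-class].
#' @param X samples x input matrix with entries in \[0, 1\] (scale raw
#'   absorbance with [scaleToUnitInterval()] first; the sigmoid decoder
#'   cannot reconstruct values outside the unit interval).
#' @return named list `total`, `recon`, `sparsity`.
#' @export
saeLoss <- function(params, X) {
  f <- saeForward(params, checkScaled(X))
  list(total = f$recon + f$sparsity, recon = f$recon, sparsity = f$sparsity)
}

checkScaled <- function(X) {
  X <- checkMatrix(X)
  if (any(X < 0 | X > 1)) {
    stop("input entries outside [0, 1]; scale with scaleToUnitInterval() first")
  }
  X
}

# forward pass + loss pieces; optionally a fixed rhoHat (EMA in minibatch mode)
saeForward <- function(params, X, rhoHat = NULL) {
  H <- saeEncode(params, X)
  Z <- saeDecode(params, H)
  if (is.null(rhoHat)) rhoHat <- colMeans(H)
  recon <- 0.5 * sum((Z - X)^2)
  sparsity <- params@beta * klDivergence(params@rho, rhoHat)
  list(H = H, Z = Z, rhoHat = rhoHat, recon = recon, sparsity = sparsity)
}

# analytic gradient of saeLoss w.r.t. all four parameter blocks.
# rhoHatN = number of samples behind rhoHat (full batch: nrow(X)).
saeGradient <- function(params, X, fwd = NULL) {
  X <- checkMatrix(X)
  if (is.null(fwd)) fwd <- saeForward(params, X)
  H <- fwd$H; Z <- fwd$Z
  eps <- 1e-10
  r <- pmin(pmax(fwd$rhoHat, eps), 1 - eps)
  dZ <- (Z - X) * Z * (1 - Z)
  gW2 <- crossprod(dZ, H)
  gb2 <- colSums(dZ)
  dH <- dZ %*% params@W2
  sparseTerm <- params@beta *
    (-params@rho / r + (1 - params@rho) / (1 - r)) / nrow(X)
  dH <- sweep(dH, 2, sparseTerm, "+")
  dA1 <- dH * H * (1 - H)
  list(W1 = crossprod(dA1, X), b1 = colSums(dA1), W2 = gW2, b2 = gb2)
}

# Glorot-uniform initialised SAEParams
initSAEParams <- function(dIn, dHidden, rho, beta, seed, initScale = 1) {
  withSeed(seed, {
    r1 <- initScale * sqrt(6 / (dIn + dHidden))
    W1 <- matrix(runif(dHidden * dIn, -r1, r1), dHidden, dIn)
    W2 <- matrix(runif(dIn * dHidden, -r1, r1), dIn, dHidden)
  })
  methods::new("SAEParams", W1 = W1, b1 = numeric(dHidden), W2 = W2,
               b2 = numeric(dIn), rho = rho, beta = beta)
}

#' Train one sparse auto-encoder layer
#'
#' Plain first-order gradient descent on the sparse reconstruction loss.
#' Because the reconstruction term is a sum over samples, the descent step
#' is normalised by the batch size (`learningRate` is a per-sample step),
#' which keeps a given learning rate stable across dataset sizes.
#' Deterministic given the seed in `opts`. Training aborts with an error if
#' the loss diverges to a non-finite value.
#'
#' @param X samples x input matrix, entries in \[0, 1\].
#' @param dHidden number of hidden units.
#' @param rho target sparsity (default 0.05).
#' @param beta sparsity weight (default 3).
#' @param opts a [trainOptions()] list.
#' @return list with `params` (an [SAEParams-class]) and `history`
#'   (data.frame of per-epoch `total`, `recon`, `sparsity`).
#' @export
trainSAE <- function(X, dHidden, rho = 0.05, beta = 3,
                     opts = trainOptions()) {
  X <- checkScaled(X)
  if (dHidden < 1L) stop("dHidden must be >= 1")
  params <- initSAEParams(ncol(X), dHidden, rho, beta, opts$seed,
                          opts$initScale)
  N <- nrow(X)
  fullBatch <- is.null(opts$batchSize) || opts$batchSize >= N
  history <- data.frame(total = numeric(opts$epochs),
                        recon = numeric(opts$epochs),
                        sparsity = numeric(opts$epochs))
  ema <- rep(rho, dHidden)
  withSeed(opts$seed + 1L, {
    for (epoch in seq_len(opts$epochs)) {
      if (fullBatch) {
        fwd <- saeForward(params, X)
        g <- saeGradient(params, X, fwd)
        loss <- fwd$recon + fwd$sparsity
        step <- opts$learningRate / N
        params@W1 <- params@W1 - step * g$W1
        params@b1 <- params@b1 - step * g$b1
        params@W2 <- params@W2 - step * g$W2
        params@b2 <- params@b2 - step * g$b2
      } else {
        ord <- sample.int(N)
        loss <- 0
        for (start in seq(1, N, by = opts$batchSize)) {
          rows <- ord[start:min(start + opts$batchSize - 1L, N)]
          Xb <- X[rows, , drop = FALSE]
          Hb <- saeEncode(params, Xb)
          ema <- 0.99 * ema + 0.01 * colMeans(Hb)
          fwd <- saeForward(params, Xb, rhoHat = ema)
          g <- saeGradient(params, Xb, fwd)
          loss <- loss + fwd$recon + fwd$sparsity
          step <- opts$learningRate / nrow(Xb)
          params@W1 <- params@W1 - step * g$W1
          params@b1 <- params@b1 - step * g$b1
          params@W2 <- params@W2 - step * g$W2
          params@b2 <- params@b2 - step * g$b2
        }
      }
      if (!is.finite(loss)) {
        stop(sprintf(
          "SAE training diverged at epoch %d (learning rate %g)",
          epoch, opts$learningRate))
      }
      if (fullBatch) {
        # loss at the start of the epoch; one forward pass per update
        history$total[epoch] <- fwd$recon + fwd$sparsity
        history$recon[epoch] <- fwd$recon
        history$sparsity[epoch] <- fwd$sparsity
      } else {
        l <- saeLoss(params, X)
        history$total[epoch] <- l$total
        history$recon[epoch] <- l$recon
        history$sparsity[epoch] <- l$sparsity
      }
    }
  })
  list(params = params, history = history)
}
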