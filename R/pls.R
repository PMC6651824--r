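#' Partial least squares regression (SIMPLS)
#'
#' Fits a PLS regression of a (possibly multi-column) response on a wide
#' predictor matrix by the SIMPLS algorithm: successive weight vectors are
#' the dominant left singular vectors of the deflated cross-covariance
#' `X'Y`, with deflation performed through an orthonormal basis of the
#' X-loading space. Classification problems are cast as one-hot
#' multi-response regression before calling this.
#'
#' @param X N x P predictor matrix.
#' @param Y N x q response matrix (or vector).
#' @param nComponents number of latent components, `<= min(N - 1, P)`.
#' @return list of class `"PLSModel"`: `coefficients` (P x q, for centered
#'   X and Y), `xMeans`, `yMeans`, `scores`, `weights`, plus the component
#'   count.
#' @seealso [predictPLS()], [rmsecv()]
#' @export
plsFit <- function(X, Y, nComponents) {
  X <- checkMatrix(X)
  Y <- as.matrix(Y)
  N <- nrow(X); P <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != N) stop("X and Y must have the same number of rows")
  if (nComponents > min(N - 1L, P)) {
    stop(sprintf("nComponents must be <= min(N - 1, P) = %d",
                 min(N - 1L, P)))
  }
  if (all(apply(Y, 2, stats::sd) == 0)) stop("response has zero variance")
  xMeans <- colMeans(X)
  yMeans <- colMeans(Y)
  Xc <- sweep(X, 2, xMeans)
  Yc <- sweep(Y, 2, yMeans)
  S <- crossprod(Xc, Yc)                      # P x q cross-covariance
  R <- matrix(0, P, nComponents)              # X weights
  TT <- matrix(0, N, nComponents)             # X scores
  Q <- matrix(0, q, nComponents)              # Y loadings
  V <- matrix(0, P, nComponents)              # orthonormal deflation basis
  for (a in seq_len(nComponents)) {
    r <- svd(S, nu = 1, nv = 0)$u[, 1]
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {
      # X deflated to numerical zero: truncate the decomposition
      R <- R[, seq_len(a - 1L), drop = FALSE]
      TT <- TT[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[, seq_len(a - 1L), drop = FALSE]
      break
    }
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)
    qa <- crossprod(Yc, t)
    v <- p
    if (a > 1L) v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], p)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; Q[, a] <- qa; V[, a] <- v
  }
  B <- R %*% t(Q)
  structure(list(coefficients = B, xMeans = xMeans, yMeans = yMeans,
                 scores = TT, weights = R, nComponents = ncol(R)),
            class = "PLSModel")
}

#' Predict from a fitted PLS model
#'
#' @param fit a `"PLSModel"` from [plsFit()].
#' @param X new predictor matrix with the same columns as at fit time.
#' @return N x q matrix of predictions.
#' @export
predictPLS <- function(fit, X) {
  X <- checkMatrix(X)
  sweep(sweep(X, 2, fit$xMeans) %*% fit$coefficients, 2, fit$yMeans, "+")
}

#' Cross-validated root mean squared error of a PLS model
#'
#' Pools squared prediction errors over all held-out samples and response
#' columns of a stratified K-fold split and returns the square root of
#' their mean. When `Y` is a one-hot indicator matrix the folds are
#' stratified on the implied class; otherwise folds are random.
#'
#' @param X predictors, `Y` responses as in [plsFit()].
#' @param Y response matrix.
#' @param nComponents PLS components used in every training fold.
#' @param nFolds number of folds (default 5).
#' @param seed fold seed; the result is deterministic given it.
#' @return scalar RMSECV.
#' @export
rmsecv <- function(X, Y, nComponents, nFolds = 5L, seed = 1L) {
  X <- checkMatrix(X)
  Y <- as.matrix(Y)
  oneHotLike <- all(Y %in% c(0, 1)) && all(rowSums(Y) == 1) && ncol(Y) > 1
  labels <- if (oneHotLike) max.col(Y) - 1L else rep(0L, nrow(Y))
  folds <- makeFolds(labels, nFolds = nFolds, seed = seed)
  sse <- 0
  for (kf in seq_len(nFolds)) {
    trn <- folds$fold != kf
    if (nComponents > min(sum(trn) - 1L, ncol(X))) {
      stop(sprintf("nComponents = %d infeasible in training fold %d",
                   nComponents, kf))
    }
    fit <- plsFit(X[trn, , drop = FALSE], Y[trn, , drop = FALSE],
                  nComponents)
    pred <- predictPLS(fit, X[!trn, , drop = FALSE])
    sse <- sse + sum((pred - Y[!trn, , drop = FALSE])^2)
  }
  sqrt(sse / length(Y))
}
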