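# central finite-difference gradient of a scalar function over a flat vector
numGrad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

relErr <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(b)))
}

# naive per-element matrix product + sigmoid, the loop oracle for encode/decode
loopAffineSigmoid <- function(X, W, b) {
  out <- matrix(0, nrow(X), nrow(W))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(W))) {
      s <- b[j]
      for (m in seq_len(ncol(X))) s <- s + W[j, m] * X[i, m]
      out[i, j] <- 1 / (1 + exp(-s))
    }
  }
  out
}

# independent NIPALS PLS (orthogonal-scores algorithm); coincides with SIMPLS
# for a single response column, which is how the cross-check uses it
nipalsPLS <- function(X, y, nComponents) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  P <- ncol(X)
  W <- matrix(0, P, nComponents)
  Pl <- matrix(0, P, nComponents)
  q <- numeric(nComponents)
  for (a in seq_len(nComponents)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p)
    f <- f - qa * t
    W[, a] <- w; Pl[, a] <- p; q[a] <- qa
  }
  B <- W %*% solve(crossprod(Pl, W), q)
  list(coefficients = B, xMeans = xm, yMean = ym)
}

# brute-force KNN oracle: per test point, sort all distances with a plain
# loop and take the majority among the k nearest
knnBrute <- function(trainX, trainY, testX, k) {
  pred <- integer(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- numeric(nrow(trainX))
    for (j in seq_len(nrow(trainX))) {
      d[j] <- sqrt(sum((testX[i, ] - trainX[j, ])^2))
    }
    nn <- trainY[order(d)][seq_len(k)]
    tab <- table(nn)
    pred[i] <- as.integer(names(tab)[which.max(tab)])
  }
  pred
}

# small labelled spectral fixture with well-separated classes
tinySpectra <- function(n = 6L, p = 8L, seed = 1L) {
  set.seed(seed)
  lab <- rep(0:1, each = n / 2)
  X <- matrix(runif(n * p, 0.2, 0.4), n, p)
  X[lab == 1, 1:3] <- X[lab == 1, 1:3] + 1
  SpectralSet(seq(4000, 550, length.out = p), X, lab)
}
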