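test_that("greedy pretraining chains encoder shapes", {
  set.seed(1)
  X <- matrix(runif(30 * 8), 30, 8)
  enc <- stackPretrain(X, c(4L, 2L),
                       opts = trainOptions(epochs = 30, learningRate = 0.5,
                                           seed = 2))
  expect_length(enc, 2L)
  expect_equal(dim(enc[[1]]$W), c(4L, 8L))
  expect_equal(dim(enc[[2]]$W), c(2L, 4L))

  # a one-layer stack is exactly the encoder half of trainSAE
  one <- stackPretrain(X, 4L, opts = trainOptions(epochs = 30,
                                                  learningRate = 0.5,
                                                  seed = 2))
  direct <- trainSAE(X, 4L, opts = trainOptions(epochs = 30,
                                                learningRate = 0.5,
                                                seed = 2))
  expect_identical(one[[1]]$W, direct$params@W1)
  expect_identical(one[[1]]$b, direct$params@b1)
})

test_that("softmax probabilities are uniform, shift-invariant, normalized", {
  F <- matrix(rnorm(10 * 4), 10, 4)
  expect_true(all(abs(softmaxProbs(matrix(0, 13, 4), F) - 1 / 13) < 1e-15))

  set.seed(2)
  th <- matrix(rnorm(3 * 4), 3, 4)
  P1 <- softmaxProbs(th, F)
  P2 <- softmaxProbs(sweep(th, 2, rnorm(4), "+"), F)  # add constant vector
  expect_equal(P1, P2, tolerance = 1e-12)
  expect_true(all(abs(rowSums(P1) - 1) <= 1e-12))

  # 2-class scalar feature with theta = (1, 0) reduces to the logistic
  x <- seq(-3, 3, 0.5)
  P <- softmaxProbs(matrix(c(1, 0), 2, 1), matrix(x, ncol = 1))
  expect_equal(P[, 1], sigmoid(x), tolerance = 1e-12)
  expect_error(softmaxProbs(th, F[, 1:2]), "match")
})

test_that("supervised loss has its closed forms and matches a loop oracle", {
  # uniform predictions: loss = ln k
  m0 <- newSSAEModel(list(), 13, lambda = 0, inputDim = 4)
  X <- matrix(rnorm(9 * 4), 9, 4)
  y <- rep(0:2, 3)
  expect_equal(supervisedLoss(m0, X, y), log(13), tolerance = 1e-12)

  # near-perfect one-hot predictions at lambda 0: loss ~ 0
  mSep <- newSSAEModel(list(), 2, lambda = 0, inputDim = 1)
  mSep@theta <- matrix(c(-500, 0, 500, 0), 2, 2, byrow = TRUE)
  Xs <- matrix(c(-1, -2, 1, 2), ncol = 1)
  expect_lt(supervisedLoss(mSep, Xs, c(0, 0, 1, 1)), 1e-12)
  expect_error(supervisedLoss(m0, X, c(0, 1, 99)), "labels")

  # loop oracle through a real encoder stack
  set.seed(3)
  enc <- list(list(W = matrix(rnorm(12, sd = 0.5), 3, 4), b = rnorm(3)))
  m <- newSSAEModel(enc, 3, lambda = 0.01)
  m@theta <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4)
  yy <- c(0, 1, 2, 1, 0)
  XX <- matrix(runif(5 * 4), 5, 4)
  manual <- 0
  for (i in 1:5) {
    h <- 1 / (1 + exp(-(enc[[1]]$W %*% XX[i, ] + enc[[1]]$b)))
    s <- m@theta %*% c(h, 1)
    pr <- exp(s - max(s)); pr <- pr / sum(pr)
    manual <- manual - log(pr[yy[i] + 1]) / 5
  }
  manual <- manual + 0.01 / 2 * sum(m@theta^2)
  expect_lt(abs(supervisedLoss(m, XX, yy) - manual), 1e-10)
})

test_that("the supervised gradient matches finite differences everywhere", {
  set.seed(4)
  enc <- list(list(W = matrix(rnorm(24, sd = 0.4), 4, 6), b = rnorm(4)),
              list(W = matrix(rnorm(12, sd = 0.4), 3, 4), b = rnorm(3)))
  m <- newSSAEModel(enc, 3, lambda = 0.05)
  m@theta <- matrix(rnorm(3 * 4, sd = 0.3), 3, 4)
  X <- matrix(runif(5 * 6), 5, 6)
  y <- c(0, 1, 2, 0, 1)
  g <- ssaeSpectra:::supervisedGradient(m, X, y)

  fTheta <- function(v) {
    mm <- m; mm@theta <- matrix(v, 3, 4); supervisedLoss(mm, X, y)
  }
  expect_lt(relErr(as.numeric(g$theta),
                   numGrad(fTheta, as.numeric(m@theta))), 1e-5)
  for (l in 1:2) {
    fW <- function(v) {
      mm <- m; mm@encoders[[l]]$W <- matrix(v, nrow(enc[[l]]$W))
      supervisedLoss(mm, X, y)
    }
    fb <- function(v) {
      mm <- m; mm@encoders[[l]]$b <- v; supervisedLoss(mm, X, y)
    }
    expect_lt(relErr(as.numeric(g$encoders[[l]]$W),
                     numGrad(fW, as.numeric(enc[[l]]$W))), 1e-5)
    expect_lt(relErr(g$encoders[[l]]$b, numGrad(fb, enc[[l]]$b)), 1e-5)
  }
})

test_that("fine-tuning separates separable classes and is deterministic", {
  set.seed(5)
  ds <- tinySpectra(n = 20, p = 6, seed = 5)
  sc <- scaleToUnitInterval(spectra(ds))
  enc <- stackPretrain(sc$scaled, 4L,
                       opts = trainOptions(epochs = 50, learningRate = 0.5,
                                           seed = 1))
  m <- newSSAEModel(enc, 2, lambda = 0)
  ft <- fineTune(m, sc$scaled, classLabels(ds),
                 trainOptions(epochs = 500, learningRate = 2))
  expect_equal(accuracy(predictClasses(ft$model, sc$scaled),
                        classLabels(ds)), 100)
  ft2 <- fineTune(m, sc$scaled, classLabels(ds),
                  trainOptions(epochs = 500, learningRate = 2))
  expect_identical(ft$history, ft2$history)

  # training loss never rises by more than 1% at the default step size
  ft3 <- fineTune(m, sc$scaled, classLabels(ds))
  inc <- diff(ft3$history) / head(ft3$history, -1)
  expect_true(all(inc <= 0.01))
})

test_that("heavy weight decay collapses theta and predictions to uniform", {
  set.seed(6)
  ds <- tinySpectra(n = 12, p = 5, seed = 6)
  sc <- scaleToUnitInterval(spectra(ds))
  enc <- stackPretrain(sc$scaled, 3L,
                       opts = trainOptions(epochs = 40, learningRate = 0.5,
                                           seed = 1))
  m <- newSSAEModel(enc, 2, lambda = 50)
  ft <- fineTune(m, sc$scaled, classLabels(ds),
                 trainOptions(epochs = 500, learningRate = 0.02))
  expect_lt(sqrt(sum(ft$model@theta^2)), 0.05)
  F <- ssaeSpectra:::ssaeForward(ft$model@encoders, sc$scaled)$features
  P <- softmaxProbs(ft$model@theta, cbind(F, 1))
  expect_true(all(abs(P - 0.5) < 0.05))
})

test_that("prediction breaks exact ties toward the smaller class index", {
  m <- newSSAEModel(list(), 3, inputDim = 2)   # all-zero theta: uniform
  X <- matrix(rnorm(8), 4, 2)
  expect_true(all(predictClasses(m, X) == 0L))
  m@theta[2, ] <- c(5, 5, 0)   # class 1 dominant for positive features
  expect_equal(predictClasses(m, matrix(c(1, 1), 1)), 1L)
})
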