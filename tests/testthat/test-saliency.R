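test_that("softmax input Jacobian has its closed forms", {
  # logistic reduction: k = 2, scalar feature, theta = (1, 0), x = 0
  expect_equal(softmaxInputJacobian(matrix(c(1, 0), 2, 1), 0, 0L), 0.25)
  # identical rows: probability constant at 1/k, zero gradient
  th <- matrix(1.3, 4, 3)
  expect_equal(softmaxInputJacobian(th, rnorm(3), 2L), rep(0, 3))
  expect_error(softmaxInputJacobian(th, rnorm(3), 7L), "range")
})

test_that("the Jacobian matches finite differences of the probabilities", {
  set.seed(1)
  th <- matrix(rnorm(4 * 5), 4, 5)
  x <- rnorm(5)
  for (j in 0:3) {
    fd <- numGrad(function(v)
      softmaxProbs(th, matrix(v, 1))[1, j + 1], x)
    expect_lt(relErr(softmaxInputJacobian(th, x, j), fd), 1e-6)
  }
})

test_that("the stable form equals the corrected quotient-rule expression", {
  # literal expansion with exponent (theta_j + theta_l)' x over the squared
  # normalizer; equals the stable form P_j (theta_j - sum_l P_l theta_l)
  set.seed(2)
  for (rep in 1:5) {
    k <- 3 + rep %% 3; d <- 4
    th <- matrix(rnorm(k * d, sd = 0.5), k, d)
    x <- rnorm(d, sd = 0.5)
    s <- drop(th %*% x)
    literal <- rep(0, d)
    for (l in seq_len(k)) {
      literal <- literal + (th[1, ] - th[l, ]) * exp(s[1] + s[l])
    }
    literal <- literal / sum(exp(s))^2
    expect_lt(relErr(softmaxInputJacobian(th, x, 0L), literal), 1e-10)
  }
})

makeTrainedTiny <- function(seed = 3) {
  set.seed(seed)
  ds <- tinySpectra(n = 16, p = 7, seed = seed)
  sc <- scaleToUnitInterval(spectra(ds))
  enc <- stackPretrain(sc$scaled, c(4L, 3L),
                       opts = trainOptions(epochs = 40, learningRate = 0.5,
                                           seed = seed))
  m <- newSSAEModel(enc, 2, lambda = 0.001)
  ft <- fineTune(m, sc$scaled, classLabels(ds),
                 trainOptions(epochs = 200, learningRate = 1))
  list(model = ft$model, X = sc$scaled, y = classLabels(ds), ds = ds)
}

test_that("per-sample input gradients match finite differences end to end", {
  tt <- makeTrainedTiny()
  G <- ssaeSpectra:::perSampleInputGradients(tt$model, tt$X, tt$y)
  for (i in c(1, 9)) {
    fd <- numGrad(function(v) {
      Xi <- matrix(v, 1)
      F <- ssaeSpectra:::ssaeForward(tt$model@encoders, Xi)$features
      P <- softmaxProbs(tt$model@theta, cbind(F, 1))
      -log(P[1, tt$y[i] + 1])
    }, tt$X[i, ])
    expect_lt(relErr(G[i, ], fd), 1e-5)
  }
})

test_that("dead input paths receive exactly zero saliency", {
  tt <- makeTrainedTiny()
  m <- tt$model
  m@encoders[[1]]$W[, 4] <- 0          # input variable 4 disconnected
  G <- ssaeSpectra:::perSampleInputGradients(m, tt$X, tt$y)
  expect_true(all(G[, 4] == 0))
  sal <- guidedBackward(m, tt$X, tt$y)
  expect_identical(sal@normalized[4], 0)
})

test_that("saliency requires labels and a trained model", {
  tt <- makeTrainedTiny()
  expect_error(guidedBackward(tt$model, tt$X), "labels")
  untrained <- newSSAEModel(tt$model@encoders, 2)
  expect_error(guidedBackward(untrained, tt$X, tt$y), "untrained")
})

test_that("normalization is idempotent and capped at magnitude one", {
  tt <- makeTrainedTiny()
  sal <- guidedBackward(tt$model, tt$X, tt$y)
  expect_equal(max(abs(sal@normalized)), 1)
  renorm <- sal@normalized / max(abs(sal@normalized))
  expect_identical(renorm, sal@normalized)
})

test_that("selection keeps thresholded local extrema with documented ties", {
  mk <- function(v) methods::new("GuidedSaliency", raw = v,
                                 normalized = v / max(abs(v)),
                                 aggregation = "classMeanMax",
                                 nSamples = 1L,
                                 wavenumbers = rev(seq_along(v)))
  s <- mk(c(0.2, 0.9, 0.3, -0.7, -0.2))
  expect_equal(selectedIndices(selectWavenumbers(s, 0.5 / 0.9 * 0.9)),
               c(2L, 4L))

  # plateau resolves to the leftmost index
  s2 <- mk(c(0.1, 0.8, 0.8, 0.8, 0.1))
  expect_equal(selectedIndices(selectWavenumbers(s2, 0.5)), 2L)

  # threshold 1.0 selects at most one (here: none, strict inequality)
  expect_lte(length(selectedIndices(selectWavenumbers(s, 1.0))), 1L)

  # monotone in the threshold
  s3 <- mk(sin(seq(0, 20, length.out = 60)) * seq(0.2, 1, length.out = 60))
  prev <- selectedIndices(selectWavenumbers(s3, 0.3))
  for (th in c(0.5, 0.7, 0.9)) {
    cur <- selectedIndices(selectWavenumbers(s3, th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }

  # all-zero saliency: empty selection is a valid result
  z <- methods::new("GuidedSaliency", raw = numeric(5),
                    normalized = numeric(5), aggregation = "mean",
                    nSamples = 1L, wavenumbers = 5:1)
  expect_length(selectedIndices(selectWavenumbers(z, 0.5)), 0L)
  expect_error(selectWavenumbers(s, 0), "threshold")
})

test_that("selection fractions reproduce the printed arithmetic", {
  expect_equal(selectionFraction(38, 7157), 0.531)
  expect_equal(selectionFraction(300, 7157), 4.192)
  expect_equal(selectionFraction(0, 7157), 0)
  expect_error(selectionFraction(5, 0), "positive")
  expect_error(selectionFraction(-1, 10), "0..nTotal")
})

test_that("saliency concentrates in planted informative bands", {
  cfg <- syntheticSpectraConfig(nPoints = 300, nClasses = 5, nPerClass = 10,
                                noiseSd = 0.01, seed = 21)
  sim <- generateSpectra(cfg)
  fit <- trainSSAE(sim$dataset, layerSizes = c(16L, 8L),
                   pretrainOpts = trainOptions(epochs = 60,
                                               learningRate = 0.1, seed = 1),
                   finetuneOpts = trainOptions(epochs = 600,
                                               learningRate = 1, seed = 1))
  sal <- guidedBackward(fit$model, sim$dataset)
  inband <- seq_len(300) %in% sim$groundTruth
  expect_gt(mean(abs(sal@normalized[inband])),
            mean(abs(sal@normalized[!inband])))
})
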