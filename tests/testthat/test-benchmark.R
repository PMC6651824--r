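test_that("accuracy is plain percent agreement", {
  expect_equal(accuracy(1:5, 1:5), 100)
  expect_equal(accuracy(1:4, 5:8), 0)
  expect_equal(accuracy(c(rep(0, 47), rep(1, 3)), rep(0, 50)), 94)
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("vectorised KNN equals the brute-force oracle", {
  set.seed(1)
  trainX <- matrix(rnorm(40 * 6), 40, 6)
  trainY <- sample(0:1, 40, replace = TRUE)   # two classes + odd k: the
  testX <- matrix(rnorm(15 * 6), 15, 6)       # majority vote is unambiguous
  for (k in c(1, 3, 7)) {
    expect_identical(ssaeSpectra:::knnPredict(trainX, trainY, testX, k),
                     knnBrute(trainX, trainY, testX, k))
  }
})

test_that("KNN cross-validation is exact on separated clouds", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, 0, 0.2), 12, 5),
             matrix(rnorm(60, 8, 0.2), 12, 5))
  ds <- SpectralSet(seq(4000, 550, length.out = 5), X, rep(0:1, each = 12))
  folds <- makeFolds(classLabels(ds), 3, seed = 1)
  rep1 <- knnCV(ds, 3:6, folds)
  expect_equal(meanPrediction(rep1), 100)
  expect_equal(meanCalibration(rep1), 100)
  rep2 <- knnCV(ds, 3:6, folds)
  expect_identical(rep1@foldPrediction, rep2@foldPrediction)
  # infeasible k values are skipped with a record
  rep3 <- knnCV(ds, c(3, 50), folds)
  expect_equal(rep3@hyperparameters$skipped, 50)
})

test_that("the SVM grid finds separable data and nulls out under permutation", {
  set.seed(3)
  X <- rbind(matrix(rnorm(80, 0, 0.3), 16, 5),
             matrix(rnorm(80, 5, 0.3), 16, 5))
  ds <- SpectralSet(seq(4000, 550, length.out = 5), X, rep(0:1, each = 16))
  folds <- makeFolds(classLabels(ds), 3, seed = 2)
  rep1 <- svmGrid(ds, seq(-4, 8, 4), seq(-8, 0, 4), folds)
  expect_equal(meanCalibration(rep1), 100)
  expect_equal(meanPrediction(rep1), 100)
  expect_identical(rep1@foldPrediction,
                   svmGrid(ds, seq(-4, 8, 4), seq(-8, 0, 4),
                           folds)@foldPrediction)

  yPerm <- withr::with_seed(9, sample(classLabels(ds)))
  dsPerm <- SpectralSet(wavenumbers(ds), spectra(ds), yPerm)
  repPerm <- svmGrid(dsPerm, seq(-4, 8, 4), seq(-8, 0, 4),
                     makeFolds(yPerm, 3, seed = 2))
  expect_lt(meanPrediction(repPerm), 80)   # far from the separable 100%
})

test_that("CVReport means recompute from fold values and bounds hold", {
  r <- methods::new("CVReport", model = "knn",
                    hyperparameters = list(k = 3),
                    foldCalibration = c(80.1, 81.1, 78.0),
                    foldPrediction = c(61.6, 60.4, 47.8))
  expect_equal(meanCalibration(r), mean(c(80.1, 81.1, 78.0)),
               tolerance = 1e-9)
  expect_equal(meanPrediction(r), mean(c(61.6, 60.4, 47.8)),
               tolerance = 1e-9)
  expect_error(methods::new("CVReport", model = "x",
                            hyperparameters = list(),
                            foldCalibration = c(120, 50, 50),
                            foldPrediction = c(1, 2, 3)),
               "0, 100")
})

test_that("tableReport restricted to all columns equals no restriction", {
  set.seed(4)
  sim <- generateSpectra(syntheticSpectraConfig(nPoints = 30, nClasses = 3,
                                                nPerClass = 8, seed = 4))
  ds <- sim$dataset
  folds <- makeFolds(classLabels(ds), 3, seed = 3)
  selAll <- methods::new("SelectionResult", method = "all",
                         indices = seq_len(30L),
                         wavenumbers = wavenumbers(ds),
                         threshold = NA_real_, note = "")
  full <- tableReport(ds, "knn", folds, kGrid = 3:5)
  restr <- tableReport(ds, "knn", folds, selection = selAll, kGrid = 3:5)
  expect_identical(full@foldPrediction, restr@foldPrediction)
  empty <- methods::new("SelectionResult", method = "none",
                        indices = integer(0), wavenumbers = numeric(0),
                        threshold = NA_real_, note = "")
  expect_error(tableReport(ds, "knn", folds, selection = empty), "empty")
})

test_that("hyperparameter search never sees held-out labels", {
  set.seed(5)
  sim <- generateSpectra(syntheticSpectraConfig(nPoints = 25, nClasses = 3,
                                                nPerClass = 9, seed = 5))
  ds <- sim$dataset
  folds <- makeFolds(classLabels(ds), 3, seed = 4)
  clean <- tableReport(ds, "knn", folds, kGrid = 3:8)
  # poison the labels of fold-1's held-out samples: the fold-1 choice of k
  # must not move, because the inner search only touches calibration rows
  yPois <- classLabels(ds)
  yPois[folds$fold == 1] <- (yPois[folds$fold == 1] + 1L) %% 3L
  dsPois <- SpectralSet(wavenumbers(ds), spectra(ds), yPois, classNames(ds))
  pois <- tableReport(dsPois, "knn", folds, kGrid = 3:8)
  expect_identical(clean@hyperparameters$perFold[[1]],
                   pois@hyperparameters$perFold[[1]])
})

test_that("selection quality scores exact, empty, and random selections", {
  truth <- c(10:14, 40:44)
  exact <- methods::new("SelectionResult", method = "x",
                        indices = as.integer(truth),
                        wavenumbers = numeric(10),
                        threshold = NA_real_, note = "")
  q <- selectionQuality(exact, truth, 0)
  expect_equal(q$recall, 1)
  expect_equal(q$precision, 1)

  none <- methods::new("SelectionResult", method = "x",
                       indices = integer(0), wavenumbers = numeric(0),
                       threshold = NA_real_, note = "")
  q0 <- selectionQuality(none, truth, 2)
  expect_true(q0$empty)
  expect_equal(q0$recall + q0$precision, 0)
  expect_error(selectionQuality(exact, integer(0)), "non-empty")

  # random selections hit the truth at about its coverage fraction
  set.seed(6)
  P <- 2000L
  truthBig <- sort(sample.int(P, 40))        # 2% of the axis
  hits <- replicate(60, {
    sel <- methods::new("SelectionResult", method = "r",
                        indices = sort(sample.int(P, 38)),
                        wavenumbers = numeric(38),
                        threshold = NA_real_, note = "")
    selectionQuality(sel, truthBig, 0)$precision
  })
  expect_lt(abs(mean(hits) - 40 / P), 0.02)
})

test_that("the t-SNE wrapper embeds, reproduces, and keeps duplicates close", {
  set.seed(7)
  X <- rbind(matrix(rnorm(100, 0, 0.3), 10, 10),
             matrix(rnorm(100, 6, 0.3), 10, 10))
  X <- rbind(X, X[1:4, ])                    # duplicated rows
  emb <- tsneEmbed(X, seed = 3)
  expect_equal(dim(emb), c(24L, 2L))
  expect_true(all(is.finite(emb)))
  expect_identical(emb, tsneEmbed(X, seed = 3))
  dupDist <- sqrt(rowSums((emb[1:4, ] - emb[21:24, ])^2))
  allDist <- as.numeric(dist(emb))
  expect_true(all(dupDist < stats::median(allDist)))
  expect_error(tsneEmbed(X[1:3, ], seed = 1), "at least 4")
})
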