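#' Classification accuracy in percent
#'
#' @param predicted,truth equal-length label vectors.
#' @return `100 * mean(predicted == truth)`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  100 * mean(predicted == truth)
}

# Euclidean KNN with deterministic tie-breaking: majority vote among the k
# nearest; vote ties resolve to the class of the nearer neighbour, then to
# the smaller class index. Calibration predictions include the sample itself
# as its own neighbour (refit evaluation).
knnPredict <- function(trainX, trainY, testX, k) {
  trainX <- checkMatrix(trainX); testX <- checkMatrix(testX)
  if (k > nrow(trainX)) stop("k exceeds the number of training samples")
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(testX^2), rep(1, nrow(trainX))) +
    outer(rep(1, nrow(testX)), rowSums(trainX^2)) -
    2 * tcrossprod(testX, trainX)
  pred <- integer(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    ord <- order(d2[i, ], trainY)      # distance ties: smaller class first
    nn <- trainY[ord[seq_len(k)]]
    votes <- table(nn)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # tie: class of the nearest neighbour among tied classes
      pred[i] <- nn[nn %in% as.integer(top)][1]
    } else {
      pred[i] <- as.integer(top)
    }
  }
  pred
}

#' Cross-validated K-nearest-neighbour benchmark
#'
#' Euclidean KNN on raw absorbance. For every k in the grid the mean
#' held-out accuracy across folds is computed; the report covers the best k
#' (ties toward smaller k). Infeasible k values (not below the smallest
#' training-fold size) are skipped with a note.
#'
#' @param x a [SpectralSet-class].
#' @param kGrid candidate neighbourhood sizes (default `3:20`).
#' @param folds a [makeFolds()] assignment.
#' @return a [CVReport-class]; skipped k values, if any, are recorded in
#'   the `hyperparameters` list.
#' @export
knnCV <- function(x, kGrid = 3:20, folds) {
  stopifnot(methods::is(x, "SpectralSet"))
  if (!length(kGrid)) stop("kGrid must be non-empty")
  X <- spectra(x)
  y <- classLabels(x)
  K <- folds$nFolds
  minTrain <- min(vapply(seq_len(K), function(kf) sum(folds$fold != kf), 1L))
  feasible <- kGrid[kGrid < minTrain]
  skipped <- setdiff(kGrid, feasible)
  if (!length(feasible)) stop("no feasible k in the grid")
  meanPred <- vapply(feasible, function(k) {
    mean(vapply(seq_len(K), function(kf) {
      trn <- folds$fold != kf
      accuracy(knnPredict(X[trn, , drop = FALSE], y[trn],
                          X[!trn, , drop = FALSE], k), y[!trn])
    }, 1))
  }, 1)
  bestK <- feasible[which.max(meanPred)]   # which.max takes the smallest tie
  cal <- pred <- numeric(K)
  for (kf in seq_len(K)) {
    trn <- folds$fold != kf
    Xtr <- X[trn, , drop = FALSE]; ytr <- y[trn]
    cal[kf] <- accuracy(knnPredict(Xtr, ytr, Xtr, bestK), ytr)
    pred[kf] <- accuracy(knnPredict(Xtr, ytr, X[!trn, , drop = FALSE],
                                    bestK), y[!trn])
  }
  hp <- list(k = bestK)
  if (length(skipped)) hp$skipped <- skipped
  methods::new("CVReport", model = "knn", hyperparameters = hp,
               foldCalibration = cal, foldPrediction = pred)
}

fitSvm <- function(Xtr, ytr, cost, gamma) {
  tryCatch(
    e1071::svm(Xtr, factor(ytr), kernel = "radial", cost = cost,
               gamma = gamma, scale = FALSE),
    error = function(e) {
      stop(sprintf("SVM solver failed at (c = %g, g = %g): %s",
                   cost, gamma, conditionMessage(e)))
    })
}

#' Cross-validated RBF-SVM benchmark with grid search
#'
#' One-vs-one multi-class support vector machine with a radial basis
#' kernel, on raw absorbance. The penalty c and kernel width g are searched
#' over `2^cExponents` x `2^gExponents` (default integer exponents -8..8);
#' the winner maximises mean held-out accuracy, with ties toward smaller c
#' then smaller g.
#'
#' @param x a [SpectralSet-class].
#' @param cExponents,gExponents exponent grids for c and g.
#' @param folds a [makeFolds()] assignment.
#' @return a [CVReport-class] for the winning (c, g).
#' @export
svmGrid <- function(x, cExponents = -8:8, gExponents = -8:8, folds) {
  stopifnot(methods::is(x, "SpectralSet"))
  if (!length(cExponents) || !length(gExponents)) {
    stop("exponent grids must be non-empty")
  }
  X <- spectra(x)
  y <- classLabels(x)
  K <- folds$nFolds
  grid <- expand.grid(ce = sort(cExponents), ge = sort(gExponents))
  grid <- grid[order(grid$ce, grid$ge), ]
  meanPred <- vapply(seq_len(nrow(grid)), function(gi) {
    mean(vapply(seq_len(K), function(kf) {
      trn <- folds$fold != kf
      fit <- fitSvm(X[trn, , drop = FALSE], y[trn],
                    2^grid$ce[gi], 2^grid$ge[gi])
      accuracy(as.integer(as.character(
        predict(fit, X[!trn, , drop = FALSE]))), y[!trn])
    }, 1))
  }, 1)
  best <- which.max(meanPred)  # grid ordered by (c, g): ties break as stated
  cost <- 2^grid$ce[best]; gamma <- 2^grid$ge[best]
  cal <- pred <- numeric(K)
  for (kf in seq_len(K)) {
    trn <- folds$fold != kf
    fit <- fitSvm(X[trn, , drop = FALSE], y[trn], cost, gamma)
    cal[kf] <- accuracy(as.integer(as.character(
      predict(fit, X[trn, , drop = FALSE]))), y[trn])
    pred[kf] <- accuracy(as.integer(as.character(
      predict(fit, X[!trn, , drop = FALSE]))), y[!trn])
  }
  methods::new("CVReport", model = "svm",
               hyperparameters = list(c = cost, g = gamma),
               foldCalibration = cal, foldPrediction = pred)
}

#' Cross-validated report with fold-internal hyperparameter search
#'
#' Runs the full leakage-free protocol: within each fold, hyperparameters
#' are chosen by an inner cross-validation on the calibration split only,
#' the model is refitted on the whole calibration split, and evaluated on
#' the held-out prediction split. Held-out labels never influence the
#' hyperparameter choice. Optionally the dataset is first restricted to a
#' selected wavenumber subset.
#'
#' @param x a [SpectralSet-class].
#' @param model `"knn"`, `"svm"` or `"ssae"`.
#' @param folds a [makeFolds()] assignment.
#' @param selection optional [SelectionResult-class]; the model sees only
#'   the selected wavenumber columns.
#' @param kGrid,cExponents,gExponents hyperparameter grids for knn / svm.
#' @param innerFolds folds of the inner search (default 3).
#' @param layerSizes,... SSAE configuration forwarded to [trainSSAE()].
#' @return a [CVReport-class].
#' @export
tableReport <- function(x, model = c("knn", "svm", "ssae"), folds,
                        selection = NULL, kGrid = 3:20,
                        cExponents = -8:8, gExponents = -8:8,
                        innerFolds = 3L, layerSizes = c(64L, 13L), ...) {
  model <- match.arg(model)
  stopifnot(methods::is(x, "SpectralSet"))
  if (!is.null(selection)) {
    idx <- selectedIndices(selection)
    if (!length(idx)) stop("empty selection")
    x <- SpectralSet(wavenumbers(x)[idx],
                     spectra(x)[, idx, drop = FALSE],
                     classLabels(x), classNames(x))
  }
  X <- spectra(x)
  y <- classLabels(x)
  K <- folds$nFolds
  cal <- pred <- numeric(K)
  hp <- list()
  for (kf in seq_len(K)) {
    trn <- folds$fold != kf
    sub <- SpectralSet(wavenumbers(x), X[trn, , drop = FALSE], y[trn],
                       classNames(x))
    innerAssign <- makeFolds(y[trn], nFolds = innerFolds,
                             seed = folds$seed + 100L * kf)
    if (model == "knn") {
      rep <- knnCV(sub, kGrid = kGrid, folds = innerAssign)
      k <- rep@hyperparameters$k
      hp[[kf]] <- list(k = k)
      cal[kf] <- accuracy(knnPredict(X[trn, , drop = FALSE], y[trn],
                                     X[trn, , drop = FALSE], k), y[trn])
      pred[kf] <- accuracy(knnPredict(X[trn, , drop = FALSE], y[trn],
                                      X[!trn, , drop = FALSE], k), y[!trn])
    } else if (model == "svm") {
      rep <- svmGrid(sub, cExponents = cExponents, gExponents = gExponents,
                     folds = innerAssign)
      hp[[kf]] <- rep@hyperparameters
      fit <- fitSvm(X[trn, , drop = FALSE], y[trn],
                    rep@hyperparameters$c, rep@hyperparameters$g)
      cal[kf] <- accuracy(as.integer(as.character(
        predict(fit, X[trn, , drop = FALSE]))), y[trn])
      pred[kf] <- accuracy(as.integer(as.character(
        predict(fit, X[!trn, , drop = FALSE]))), y[!trn])
    } else {
      tr <- trainSSAE(sub, layerSizes = layerSizes, ...)
      hp[[kf]] <- list(layerSizes = layerSizes)
      cal[kf] <- accuracy(predictClasses(tr$model, sub), y[trn])
      held <- SpectralSet(wavenumbers(x), X[!trn, , drop = FALSE],
                          y[!trn], classNames(x))
      pred[kf] <- accuracy(predictClasses(tr$model, held), y[!trn])
    }
  }
  methods::new("CVReport", model = model,
               hyperparameters = list(perFold = hp),
               foldCalibration = cal, foldPrediction = pred)
}

#' Recall and precision of a wavenumber selection against planted bands
#'
#' Judged at band granularity: the ground truth is a set of axis indices
#' (typically contiguous runs covering planted bands). Recall is the
#' fraction of contiguous truth bands hit by at least one selected index
#' within the tolerance; precision is the fraction of selected indices
#' lying within the tolerance of some truth index. An empty selection
#' reports recall and precision 0 with `empty = TRUE`.
#'
#' @param selection a [SelectionResult-class].
#' @param groundTruth sorted integer indices of truth positions.
#' @param tolerance allowed distance in grid points (default 2).
#' @return list of class `"SelectionQuality"` with `recall`, `precision`,
#'   `nSelected` and `empty`.
#' @export
selectionQuality <- function(selection, groundTruth, tolerance = 2L) {
  if (!length(groundTruth)) stop("ground truth must be non-empty")
  idx <- selectedIndices(selection)
  if (!length(idx)) {
    return(structure(list(recall = 0, precision = 0, nSelected = 0L,
                          empty = TRUE), class = "SelectionQuality"))
  }
  gt <- sort(unique(as.integer(groundTruth)))
  bandId <- cumsum(c(1L, diff(gt) > 1L))
  bands <- split(gt, bandId)
  hit <- vapply(bands, function(b) {
    any(vapply(idx, function(p) any(abs(b - p) <= tolerance), TRUE))
  }, TRUE)
  nearTruth <- vapply(idx, function(p) any(abs(gt - p) <= tolerance), TRUE)
  structure(list(recall = mean(hit), precision = mean(nearTruth),
                 nSelected = length(idx), empty = FALSE),
            class = "SelectionQuality")
}

#' Two-dimensional t-SNE embedding (scikit-learn wrapper)
#'
#' Thin wrapper around the t-distributed stochastic neighbour embedding in
#' scikit-learn, called through the `python` interpreter on the PATH; used
#' purely for visualising raw spectra and learned hidden-layer features.
#' PCA initialisation plus a fixed `random_state` make the coordinates
#' reproducible for a given seed.
#'
#' @param features N x d matrix, N >= 4.
#' @param seed integer seed.
#' @param perplexity requested perplexity (default 30), capped below N / 3.
#' @return N x 2 matrix of finite coordinates.
#' @export
tsneEmbed <- function(features, seed = 1L, perplexity = 30) {
  features <- checkMatrix(features)
  N <- nrow(features)
  if (N < 4L) stop("need at least 4 samples for a t-SNE embedding")
  python <- Sys.which("python")
  if (!nzchar(python)) stop("no 'python' interpreter found on the PATH")
  perp <- min(perplexity, max(2, floor(N / 3) - 1L))
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(features, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.manifold import TSNE\n",
    "X = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "emb = TSNE(n_components=2, perplexity=%g, random_state=%d,\n",
    "           init='pca').fit_transform(X)\n",
    "np.savetxt(%s, emb, delimiter=',')\n"),
    deparse(fin), perp, as.integer(seed), deparse(fout))
  status <- system2(python, c("-c", shQuote(code)), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(fout) || !is.null(attr(status, "status"))) {
    stop("t-SNE subprocess failed: ", paste(status, collapse = "\n"))
  }
  out <- as.matrix(utils::read.csv(fout, header = FALSE))
  dimnames(out) <- NULL
  if (any(!is.finite(out))) stop("t-SNE produced non-finite coordinates")
  out
}
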