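#' Principal component analysis of a spectral matrix
#'
#' Column-centered PCA (no variance scaling: absorbance shares units across
#' variables) via [stats::prcomp()]. Loadings are the unit-norm principal
#' axes, one row per component.
#'
#' @param X N x P matrix.
#' @param nComponents number of components to retain,
#'   `<= min(N - 1, P)`.
#' @return list of class `"PCAResult"`: `loadings` (components x variables),
#'   `explainedVarianceRatio` (over all possible components, first
#'   `nComponents` reported), `nComponents`, `center`.
#' @export
pcaFit <- function(X, nComponents) {
  X <- checkMatrix(X)
  if (nComponents > min(nrow(X) - 1L, ncol(X))) {
    stop(sprintf("nComponents must be <= min(N - 1, P) = %d",
                 min(nrow(X) - 1L, ncol(X))))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = nComponents)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = t(pc$rotation),
                 explainedVarianceRatio = ratio[seq_len(nComponents)],
                 nComponents = as.integer(nComponents),
                 center = pc$center),
            class = "PCAResult")
}

#' PCA-loading wavenumber selection
#'
#' Scores every variable as the maximum absolute loading over the first
#' `nPcs` principal components and selects the `nSelect` highest-scoring
#' variables, restricted to local maxima of the score curve so one band
#' contributes isolated wavenumbers rather than a contiguous block. Ties
#' break toward higher wavenumber. If fewer local maxima than `nSelect`
#' exist, the extremum restriction is dropped and the fallback recorded in
#' the result's note.
#'
#' @param x a [SpectralSet-class] or N x P matrix.
#' @param nPcs number of leading components scanned (default 6).
#' @param nSelect number of variables to select (default 39).
#' @param restrictToMaxima set `FALSE` to rank all variables by score.
#' @return a [SelectionResult-class].
#' @export
pcaLoadingSelect <- function(x, nPcs = 6L, nSelect = 39L,
                             restrictToMaxima = TRUE) {
  wn <- numeric(0)
  if (methods::is(x, "SpectralSet")) {
    wn <- wavenumbers(x)
    X <- spectra(x)
  } else {
    X <- checkMatrix(x)
  }
  if (nPcs < 1L) stop("nPcs must be >= 1")
  if (nSelect > ncol(X)) stop("nSelect must be <= number of variables")
  pca <- pcaFit(X, nPcs)
  score <- apply(abs(pca$loadings), 2, max)
  note <- ""
  P <- length(score)
  pool <- seq_len(P)
  if (restrictToMaxima) {
    left <- c(-Inf, score[-P])
    right <- c(score[-1], -Inf)
    pool <- which(score >= left & score >= right)
    if (length(pool) < nSelect) {
      pool <- seq_len(P)
      note <- sprintf(
        "only %d local maxima for %d requested; extremum restriction dropped",
        length(pool), nSelect)
    }
  }
  # ties toward higher wavenumber = smaller index on the descending axis
  ord <- pool[order(-score[pool], pool)]
  idx <- sort(ord[seq_len(nSelect)])
  methods::new("SelectionResult", method = "pca-loading",
               indices = as.integer(idx),
               wavenumbers = if (length(wn)) wn[idx]
                             else numeric(length(idx)),
               threshold = as.numeric(nSelect), note = note)
}

#' Configuration for competitive adaptive reweighted sampling
#'
#' @param nRuns Monte-Carlo iterations (default 50).
#' @param nFolds folds for the per-run RMSECV (default 5).
#' @param maxComponents cap on PLS components (default 10).
#' @param sampleFraction fraction of calibration rows drawn per run
#'   (default 0.8).
#' @param seed integer seed.
#' @return list of class `"CARSConfig"`.
#' @export
carsConfig <- function(nRuns = 50L, nFolds = 5L, maxComponents = 10L,
                       sampleFraction = 0.8, seed = 1L) {
  if (nRuns < 2L) stop("nRuns must be >= 2")
  if (sampleFraction <= 0 || sampleFraction > 1) {
    stop("sampleFraction must be in (0, 1]")
  }
  if (maxComponents < 1L) stop("maxComponents must be >= 1")
  structure(list(nRuns = as.integer(nRuns), nFolds = as.integer(nFolds),
                 maxComponents = as.integer(maxComponents),
                 sampleFraction = sampleFraction, seed = as.integer(seed)),
            class = "CARSConfig")
}

# exponential decay retention ratio: r_1 = 1, r_nRuns = 2 / P
carsRetentionRatio <- function(run, nRuns, P) {
  k <- log(P / 2) / (nRuns - 1)
  a <- exp(k)
  a * exp(-k * run)
}

#' Competitive adaptive reweighted sampling over a PLS core
#'
#' Iterative wavenumber elimination driven by PLS regression coefficient
#' magnitudes. Per run: a PLS model is fitted on a Monte-Carlo subsample of
#' the calibration rows restricted to the surviving variables; variables
#' are weighted by the L2 norm of their coefficients across the one-hot
#' response columns; an exponentially decaying retention schedule (ratio 1
#' at the first run, `2/P` at the last) keeps the top-weighted variables;
#' adaptive reweighted sampling (weighted bootstrap, unique survivors) adds
#' competition among them; and the surviving set is scored by RMSECV on the
#' full data. The selection comes from the run with minimal RMSECV.
#'
#' @param x a [SpectralSet-class], or an N x P matrix if `y` is given.
#' @param y integer class labels (0-based), one-hot encoded internally.
#' @param config a [carsConfig()] list.
#' @return list with `selection` (a [SelectionResult-class]) and
#'   `diagnostics` (data.frame of per-run variable counts, RMSECV and
#'   feasibility).
#' @export
carsSelect <- function(x, y = NULL, config = carsConfig()) {
  wn <- numeric(0)
  if (methods::is(x, "SpectralSet")) {
    wn <- wavenumbers(x)
    y <- classLabels(x)
    X <- spectra(x)
  } else {
    X <- checkMatrix(x)
    y <- as.integer(y)
  }
  C <- max(y) + 1L
  if (C < 2L) stop("need at least 2 classes")
  Y <- oneHot(y, C)
  N <- nrow(X); P <- ncol(X)
  survivors <- seq_len(P)
  nSub <- max(2L, round(config$sampleFraction * N))
  runs <- data.frame(run = seq_len(config$nRuns),
                     nVars = NA_integer_, rmsecv = NA_real_,
                     feasible = FALSE)
  sets <- vector("list", config$nRuns)
  withSeed(config$seed, {
    for (i in seq_len(config$nRuns)) {
      mKeep <- max(2L, round(P * carsRetentionRatio(i, config$nRuns, P)))
      mKeep <- min(mKeep, length(survivors))
      rows <- sample.int(N, nSub)
      nc <- min(config$maxComponents, length(survivors), nSub - 1L)
      if (length(survivors) < 2L || nc < 1L) break
      fit <- plsFit(X[rows, survivors, drop = FALSE],
                    Y[rows, , drop = FALSE], nc)
      w <- sqrt(rowSums(fit$coefficients^2))
      w <- w / sum(w)
      keep <- survivors[order(-w)][seq_len(mKeep)]
      wKeep <- w[match(keep, survivors)]
      if (i > 1L && all(wKeep > 0)) {
        # adaptive reweighted sampling: mKeep weighted draws, unique kept
        drawn <- sample(keep, mKeep, replace = TRUE, prob = wKeep)
        keep <- sort(unique(drawn))
      } else {
        keep <- sort(keep)
      }
      survivors <- keep
      sets[[i]] <- survivors
      runs$nVars[i] <- length(survivors)
      ncCv <- min(config$maxComponents, length(survivors),
                  floor(N * (config$nFolds - 1) / config$nFolds) - 1L)
      if (length(survivors) >= 2L && ncCv >= 1L) {
        runs$rmsecv[i] <- rmsecv(X[, survivors, drop = FALSE], Y, ncCv,
                                 nFolds = config$nFolds,
                                 seed = config$seed + i)
        runs$feasible[i] <- TRUE
      }
    }
  })
  if (!any(runs$feasible)) stop("no feasible CARS run")
  best <- which(runs$rmsecv == min(runs$rmsecv[runs$feasible]) &
                  runs$feasible)[1]
  idx <- sets[[best]]
  sel <- methods::new("SelectionResult", method = "cars",
                      indices = as.integer(idx),
                      wavenumbers = if (length(wn)) wn[idx]
                                    else numeric(length(idx)),
                      threshold = NA_real_,
                      note = sprintf("best run %d of %d (RMSECV %.4g)",
                                     best, config$nRuns, runs$rmsecv[best]))
  list(selection = sel, diagnostics = runs)
}
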