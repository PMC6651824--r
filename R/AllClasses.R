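#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats plogis prcomp runif sd predict
#' @importFrom utils read.csv write.csv head
NULL

#' SpectralSet: a set of infrared absorbance spectra with class labels
#'
#' `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' an absorbance matrix measured on a common wavenumber axis together with an
#' integer class label per sample. Following the SummarizedExperiment
#' convention the assay stores variables (wavenumbers) in rows and samples in
#' columns; the user-facing accessor [spectra()] returns the transposed
#' samples-by-wavenumbers matrix used by all modelling functions.
#'
#' The wavenumber axis is always stored strictly descending (4000 down to
#' 550 cm^-1 for a typical mid-infrared scan), matching the convention in
#' which FTIR spectra are plotted. Class labels are 0-based integers in
#' `0..C-1`, mirroring the indicator convention of the softmax classifier.
#'
#' @section Validity:
#' * wavenumbers strictly monotone descending, no duplicates
#' * absorbance finite everywhere
#' * every label in `0..C-1` and every class has at least one sample
#' * at least 2 samples and 2 wavenumbers
#'
#' @seealso [SpectralSet()] for construction, [readSpectra()] for file input.
#' @aliases SpectralSet-class
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    return("rowData must contain a 'wavenumber' column")
  }
  if (nrow(object) < 2L || ncol(object) < 2L) {
    msg <- c(msg, "need at least 2 samples and 2 wavenumbers")
  }
  if (anyNA(wn) || any(!is.finite(wn))) {
    msg <- c(msg, "wavenumbers must be finite")
  } else if (any(diff(wn) >= 0)) {
    msg <- c(msg, "wavenumbers must be strictly descending")
  }
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (any(!is.finite(a))) {
    msg <- c(msg, "absorbance contains non-finite values")
  }
  lab <- SummarizedExperiment::colData(object)$label
  cn <- object@metadata$classNames
  if (is.null(lab) || is.null(cn)) {
    msg <- c(msg, "colData must contain 'label' and metadata 'classNames'")
  } else {
    C <- length(cn)
    if (anyNA(lab) || any(lab < 0L | lab >= C)) {
      msg <- c(msg, sprintf("labels must lie in 0..%d", C - 1L))
    } else if (length(unique(lab)) != C) {
      missing <- setdiff(seq_len(C) - 1L, unique(lab))
      msg <- c(msg, sprintf("class(es) without samples: %s",
                            paste(missing, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralSet
#'
#' @param wavenumbers numeric vector of length P, in cm^-1. Any strictly
#'   monotone order is accepted; the object stores the axis descending and
#'   reorders the absorbance columns accordingly.
#' @param absorbance numeric matrix, N samples x P wavenumbers.
#' @param labels integer vector of N class ids in `0..C-1`.
#' @param classNames optional character vector of C class names; defaults to
#'   `"class0" .. "class<C-1>"` with C inferred as `max(labels) + 1`.
#' @return A validated [SpectralSet-class] object.
#' @examples
#' x <- SpectralSet(c(4000, 2000, 550),
#'                  matrix(runif(12), 4, 3),
#'                  labels = c(0L, 0L, 1L, 1L))
#' spectra(x)
#' @export
SpectralSet <- function(wavenumbers, absorbance, labels, classNames = NULL) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance)) {
    stop("length(wavenumbers) must equal ncol(absorbance)")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(absorbance)) {
    stop("length(labels) must equal nrow(absorbance)")
  }
  if (is.unsorted(rev(wavenumbers), strictly = TRUE)) {
    ord <- order(wavenumbers, decreasing = TRUE)
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
  }
  if (is.null(classNames)) {
    classNames <- paste0("class", seq_len(max(labels) + 1L) - 1L)
  }
  a <- t(absorbance)
  rownames(a) <- format(wavenumbers, trim = TRUE, digits = 10)
  if (is.null(colnames(a))) {
    colnames(a) <- paste0("sample", seq_len(ncol(a)))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = a),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = S4Vectors::DataFrame(label = labels,
                                   className = classNames[labels + 1L]),
    metadata = list(classNames = as.character(classNames))
  )
  obj <- methods::new("SpectralSet", se)
  methods::validObject(obj)
  obj
}

#' Parameters of a single sparse auto-encoder layer
#'
#' Holds the encode/decode weights and biases of one sparse auto-encoder
#' together with its sparsity hyperparameters: the target mean activation
#' `rho` (a small value close to 0) and the weight `beta` of the
#' Kullback-Leibler sparsity penalty.
#'
#' @slot W1 encode weight matrix, hidden x input
#' @slot b1 encode bias, length hidden
#' @slot W2 decode weight matrix, input x hidden
#' @slot b2 decode bias, length input
#' @slot rho target sparsity in (0, 1)
#' @slot beta sparsity penalty weight, >= 0
#' @aliases SAEParams-class
#' @export
setClass("SAEParams",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", rho = "numeric", beta = "numeric"))

setValidity("SAEParams", function(object) {
  msg <- character()
  h <- nrow(object@W1); d <- ncol(object@W1)
  if (nrow(object@W2) != d || ncol(object@W2) != h) {
    msg <- c(msg, "W2 must be input x hidden (transpose-shaped to W1)")
  }
  if (length(object@b1) != h) msg <- c(msg, "b1 length must equal hidden size")
  if (length(object@b2) != d) msg <- c(msg, "b2 length must equal input size")
  if (!all(is.finite(object@W1), is.finite(object@b1),
           is.finite(object@W2), is.finite(object@b2))) {
    msg <- c(msg, "parameters must be finite")
  }
  if (length(object@rho) != 1L || object@rho <= 0 || object@rho >= 1) {
    msg <- c(msg, "rho must be a single value in (0, 1)")
  }
  if (length(object@beta) != 1L || object@beta < 0) {
    msg <- c(msg, "beta must be a single non-negative value")
  }
  if (length(msg)) msg else TRUE
})

#' A stacked sparse auto-encoder with softmax classification head
#'
#' The encoder layers come from greedy layerwise pretraining (decoders
#' discarded); `theta` maps the last hidden representation, augmented with a
#' constant-1 feature acting as bias, to k class scores. `lambda` is the
#' weight-decay coefficient applied to `theta` (and only `theta`) during
#' supervised fine-tuning. `scaling`, when present, is the record produced by
#' [scaleToUnitInterval()] on the training spectra and is re-applied by
#' [predictClasses()] and [guidedBackward()].
#'
#' @slot encoders list of `list(W, b)` encode parameter pairs, input-first
#' @slot theta softmax weight matrix, k x (last hidden dim + 1)
#' @slot lambda weight decay, >= 0
#' @slot layerSizes integer vector of hidden layer widths
#' @slot scaling list; per-variable affine scaling record or empty list
#' @aliases SSAEModel-class
#' @export
setClass("SSAEModel",
  representation(encoders = "list", theta = "matrix", lambda = "numeric",
                 layerSizes = "integer", scaling = "list"))

setValidity("SSAEModel", function(object) {
  msg <- character()
  d <- NA_integer_
  for (i in seq_along(object@encoders)) {
    enc <- object@encoders[[i]]
    if (!is.list(enc) || !all(c("W", "b") %in% names(enc))) {
      return("each encoder must be a list(W, b)")
    }
    if (length(enc$b) != nrow(enc$W)) {
      msg <- c(msg, sprintf("encoder %d: bias length != rows(W)", i))
    }
    if (!is.na(d) && ncol(enc$W) != d) {
      msg <- c(msg, sprintf("encoder %d: input dim %d != previous hidden %d",
                            i, ncol(enc$W), d))
    }
    d <- nrow(enc$W)
  }
  if (length(object@encoders) && ncol(object@theta) != d + 1L) {
    msg <- c(msg, "theta feature dimension must be last hidden dim + 1")
  }
  if (nrow(object@theta) < 2L) msg <- c(msg, "need k >= 2 classes")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-wavenumber saliency from guided backpropagation
#'
#' The gradient of the supervised softmax loss with respect to the input
#' spectrum, aggregated over samples, is used as a per-wavenumber importance
#' score. `normalized` is `raw` divided by its maximum absolute value so the
#' selection threshold operates on a `[-1, 1]` scale.
#'
#' @slot raw numeric vector, length P
#' @slot normalized numeric vector, length P, max |value| = 1 unless raw == 0
#' @slot aggregation how per-sample gradients were pooled
#' @slot nSamples number of samples contributing
#' @slot wavenumbers the matching axis (cm^-1), for plotting and selection
#' @aliases GuidedSaliency-class
#' @export
setClass("GuidedSaliency",
  representation(raw = "numeric", normalized = "numeric",
                 aggregation = "character", nSamples = "integer",
                 wavenumbers = "numeric"))

setValidity("GuidedSaliency", function(object) {
  msg <- character()
  if (length(object@raw) != length(object@normalized)) {
    msg <- c(msg, "raw and normalized must have equal length")
  }
  if (length(object@wavenumbers) &&
      length(object@wavenumbers) != length(object@raw)) {
    msg <- c(msg, "wavenumbers length must match raw")
  }
  if (any(object@raw != 0) &&
      abs(max(abs(object@normalized)) - 1) > 1e-12) {
    msg <- c(msg, "max |normalized| must be 1 for non-zero saliency")
  }
  if (length(msg)) msg else TRUE
})

#' A set of selected wavenumbers
#'
#' @slot method name of the selector ("ssae-gb", "pca-loading", "cars", ...)
#' @slot indices sorted 1-based indices into the wavenumber axis
#' @slot wavenumbers the corresponding cm^-1 values
#' @slot threshold threshold or requested count that produced the set (NA if
#'   not applicable)
#' @slot note free-text note, e.g. recorded fallbacks
#' @aliases SelectionResult-class
#' @export
setClass("SelectionResult",
  representation(method = "character", indices = "integer",
                 wavenumbers = "numeric", threshold = "numeric",
                 note = "character"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  idx <- object@indices
  if (anyDuplicated(idx)) msg <- c(msg, "indices must be unique")
  if (is.unsorted(idx)) msg <- c(msg, "indices must be sorted")
  if (length(idx) && any(idx < 1L)) msg <- c(msg, "indices must be >= 1")
  if (length(object@wavenumbers) != length(idx)) {
    msg <- c(msg, "wavenumbers must parallel indices")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validated accuracy report
#'
#' Fold-wise calibration-set (training folds, refit evaluation) and
#' prediction-set (held-out fold) accuracies in percent, in the shape used
#' to report cross-validated spectral classification models.
#'
#' @slot model model name
#' @slot hyperparameters named list of the chosen hyperparameters
#' @slot foldCalibration per-fold calibration accuracy (percent)
#' @slot foldPrediction per-fold prediction accuracy (percent)
#' @aliases CVReport-class
#' @export
setClass("CVReport",
  representation(model = "character", hyperparameters = "list",
                 foldCalibration = "numeric", foldPrediction = "numeric"))

setValidity("CVReport", function(object) {
  msg <- character()
  acc <- c(object@foldCalibration, object@foldPrediction)
  if (any(acc < 0 | acc > 100)) msg <- c(msg, "accuracies must be in [0, 100]")
  if (length(object@foldCalibration) != length(object@foldPrediction)) {
    msg <- c(msg, "calibration and prediction folds must align")
  }
  if (length(msg)) msg else TRUE
})
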