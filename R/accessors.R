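#' Accessors for SpectralSet objects
#'
#' @param x a [SpectralSet-class]
#' @return `wavenumbers()` the descending cm^-1 axis; `spectra()` the N x P
#'   samples-by-wavenumbers absorbance matrix; `classLabels()` the integer
#'   0-based labels; `classNames()` the class name vector; `nSamples()` /
#'   `nWavenumbers()` the dimensions.
#' @name SpectralSet-accessors
NULL

#' @rdname SpectralSet-accessors
#' @export
setMethod("wavenumbers", "SpectralSet", function(x) {
  SummarizedExperiment::rowData(x)$wavenumber
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("spectra", "SpectralSet", function(x) {
  t(SummarizedExperiment::assay(x, "absorbance"))
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("classLabels", "SpectralSet", function(x) {
  SummarizedExperiment::colData(x)$label
})

#' @rdname SpectralSet-accessors
#' @export
setMethod("classNames", "SpectralSet", function(x) x@metadata$classNames)

#' @rdname SpectralSet-accessors
#' @export
setMethod("nSamples", "SpectralSet", function(x) ncol(x))

#' @rdname SpectralSet-accessors
#' @export
setMethod("nWavenumbers", "SpectralSet", function(x) nrow(x))

setMethod("show", "SpectralSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectralSet: %d samples x %d wavenumbers (%.1f..%.1f cm^-1)\n",
              ncol(object), nrow(object), wn[1], wn[length(wn)]))
  tab <- table(classNames(object)[classLabels(object) + 1L])
  cat(sprintf("%d classes: %s\n", length(classNames(object)),
              paste(sprintf("%s(%d)", names(tab), tab), collapse = " ")))
})

#' Mean accuracies of a cross-validation report
#'
#' @param x a [CVReport-class]
#' @return arithmetic mean over folds, in percent.
#' @name CVReport-accessors
NULL

#' @rdname CVReport-accessors
#' @export
setMethod("meanCalibration", "CVReport", function(x) mean(x@foldCalibration))

#' @rdname CVReport-accessors
#' @export
setMethod("meanPrediction", "CVReport", function(x) mean(x@foldPrediction))

setMethod("show", "CVReport", function(object) {
  hp <- paste(names(object@hyperparameters),
              vapply(object@hyperparameters, function(v)
                paste(format(v, digits = 4), collapse = ","), ""),
              sep = "=", collapse = " ")
  cat(sprintf("CVReport for %s [%s]\n", object@model, hp))
  k <- length(object@foldCalibration)
  m <- rbind(Calibration = c(object@foldCalibration, meanCalibration(object)),
             Prediction = c(object@foldPrediction, meanPrediction(object)))
  colnames(m) <- c(paste0("fold", seq_len(k)), "mean")
  print(round(m, 1))
})

#' Selected axis indices of a SelectionResult
#'
#' @param x a [SelectionResult-class]
#' @return sorted integer vector of 1-based indices into the wavenumber axis.
#' @name selectedIndices
#' @export
setMethod("selectedIndices", "SelectionResult", function(x) x@indices)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d wavenumbers", object@method,
              length(object@indices)))
  if (!is.na(object@threshold)) {
    cat(sprintf(" (threshold/count %.3g)", object@threshold))
  }
  cat("\n")
  if (length(object@wavenumbers)) {
    cat("  cm^-1:", paste(round(head(object@wavenumbers, 8), 1),
                          collapse = ", "),
        if (length(object@wavenumbers) > 8) "...", "\n")
  }
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "GuidedSaliency", function(object) {
  cat(sprintf("GuidedSaliency over %d wavenumbers (aggregation: %s, n=%d)\n",
              length(object@raw), object@aggregation, object@nSamples))
})

setMethod("show", "SSAEModel", function(object) {
  cat(sprintf("SSAEModel: encoder stack %s -> softmax over %d classes\n",
              paste(object@layerSizes, collapse = " -> "),
              nrow(object@theta)))
  cat(sprintf("  weight decay lambda = %g; input scaling %s\n", object@lambda,
              if (length(object@scaling)) "stored" else "none"))
})

setMethod("show", "SAEParams", function(object) {
  cat(sprintf("SAEParams: %d -> %d (rho = %g, beta = %g)\n",
              ncol(object@W1), nrow(object@W1), object@rho, object@beta))
})
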