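#' @rdname SpectralSet-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SpectralSet-accessors
#' @export
setGeneric("nWavenumbers", function(x) standardGeneric("nWavenumbers"))

#' @rdname CVReport-accessors
#' @export
setGeneric("meanCalibration", function(x) standardGeneric("meanCalibration"))

#' @rdname CVReport-accessors
#' @export
setGeneric("meanPrediction", function(x) standardGeneric("meanPrediction"))

#' @rdname selectedIndices
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))
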