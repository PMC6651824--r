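Package: ssaeSpectra
Title: Stacked Sparse Auto-Encoders for Infrared Spectral Classification
    and Wavenumber Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classification of Fourier-transform infrared (FTIR) absorbance
    spectra with stacked sparse auto-encoders (SSAE) fine-tuned through a
    softmax classifier, and selection of informative wavenumbers from the
    gradient of the supervised loss with respect to the input spectrum
    ("guided backward" saliency). Includes the standard chemometric
    baselines for comparison (k-nearest neighbours, RBF support vector
    machines, PCA-loading selection, and competitive adaptive reweighted
    sampling over a SIMPLS partial least squares core), stratified
    cross-validated benchmarking, and a synthetic multi-class FTIR spectrum
    generator with planted informative absorption bands for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
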