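#' Read a spectral dataset from delimited text
#'
#' Reads the package's plain CSV dialect: the header row carries the
#' wavenumber of each absorbance column plus one label column (named
#' `"label"` by default); each subsequent row is one sample. Gzip-compressed
#' files (`.gz`) are decompressed transparently. The wavenumber axis is
#' reordered to the descending storage convention regardless of file order.
#'
#' @param path path to a CSV (optionally gzipped) file.
#' @param labelColumn name of the label column; default `"label"`.
#' @param classNames optional class names; default inferred from the labels.
#' @return a validated [SpectralSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, labelColumn = "label", classNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (!labelColumn %in% names(raw)) {
    stop("no '", labelColumn, "' column in ", path)
  }
  wnCols <- names(raw)[names(raw) != labelColumn]
  wn <- suppressWarnings(as.numeric(wnCols))
  if (anyNA(wn)) {
    stop("non-numeric wavenumber header: ",
         paste(wnCols[is.na(wn)], collapse = ", "))
  }
  if (anyDuplicated(wn)) {
    stop("duplicate wavenumbers in header: ",
         paste(unique(wn[duplicated(wn)]), collapse = ", "))
  }
  absC <- as.matrix(raw[wnCols])
  abs <- suppressWarnings(array(as.numeric(absC), dim(absC)))
  bad <- which(is.na(abs) & !(absC %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric cell '%s' at row %d, column '%s'",
                 absC[bad[1, 1], bad[1, 2]], bad[1, 1], wnCols[bad[1, 2]]))
  }
  if (any(!is.finite(abs))) {
    bad <- which(!is.finite(abs), arr.ind = TRUE)
    stop(sprintf("non-finite absorbance at row %d, column '%s'",
                 bad[1, 1], wnCols[bad[1, 2]]))
  }
  labRaw <- raw[[labelColumn]]
  lab <- suppressWarnings(as.integer(labRaw))
  if (anyNA(lab)) {
    stop("malformed label value '", labRaw[which(is.na(lab))[1]], "' at row ",
         which(is.na(lab))[1])
  }
  SpectralSet(wn, abs, lab, classNames = classNames)
}

#' Write a spectral dataset as delimited text
#'
#' Inverse of [readSpectra()]: wavenumbers as column headers, one sample per
#' row, labels in a `"label"` column. Numeric values are written with 15
#' significant digits so a read/write round trip reproduces the data to
#' better than 1e-12 relative error. Paths ending in `.gz` are compressed.
#'
#' @param x a [SpectralSet-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path) {
  stopifnot(methods::is(x, "SpectralSet"))
  methods::validObject(x)
  df <- as.data.frame(format(spectra(x), digits = 15, trim = TRUE,
                             scientific = TRUE))
  names(df) <- format(wavenumbers(x), digits = 15, trim = TRUE)
  df$label <- classLabels(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ok <- tryCatch({
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `nFolds` folds such that, within every
#' class, fold sizes differ by at most one sample. The assignment is a
#' deterministic function of `(labels, nFolds, seed)`.
#'
#' @param labels integer class labels (0-based).
#' @param nFolds number of folds K, >= 2. Three folds reproduce the
#'   three-fold cross-validation protocol used throughout the benchmarks.
#' @param seed integer RNG seed.
#' @return a list of class `"FoldAssignment"` with elements `fold` (integer
#'   vector of fold ids in `1..K`), `nFolds` and `seed`.
#' @examples
#' f <- makeFolds(rep(0:1, each = 6), nFolds = 3, seed = 1)
#' table(rep(0:1, each = 6), f$fold)
#' @export
makeFolds <- function(labels, nFolds = 3L, seed = 1L) {
  labels <- as.integer(labels)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  counts <- table(labels)
  small <- counts[counts < nFolds]
  if (length(small)) {
    stop("class(es) with fewer samples than folds: ",
         paste(names(small), collapse = ", "))
  }
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(sample.int(nFolds), length.out = length(idx))
    }
  })
  structure(list(fold = fold, nFolds = nFolds, seed = as.integer(seed)),
            class = "FoldAssignment")
}

#' Affine scaling of absorbance into a sub-interval of (0, 1)
#'
#' Maps each variable (wavenumber column) linearly onto `[lo, hi]`. The
#' sigmoid decoder of a sparse auto-encoder can only reconstruct values in
#' (0, 1), so spectra are scaled before auto-encoder training; distance- and
#' kernel-based baselines operate on raw absorbance. Constant columns map to
#' the midpoint `(lo + hi) / 2`. The returned record suffices to invert the
#' map exactly and to apply it to new spectra.
#'
#' @param x numeric matrix (samples x variables) or [SpectralSet-class].
#' @param lo,hi target interval bounds, `0 < lo < hi < 1`.
#' @return list with `scaled` (same type as `x`) and `record` (list with
#'   `lo`, `hi`, per-column `min`, `max` and a `constant` flag).
#' @seealso [applyScaling()], [invertScaling()]
#' @export
scaleToUnitInterval <- function(x, lo = 0.05, hi = 0.95) {
  if (!(lo > 0 && hi < 1 && lo < hi)) stop("need 0 < lo < hi < 1")
  isSet <- methods::is(x, "SpectralSet")
  m <- if (isSet) spectra(x) else checkMatrix(x)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  constant <- maxs == mins
  record <- list(lo = lo, hi = hi, min = mins, max = maxs,
                 constant = constant)
  scaled <- applyScaling(m, record)
  if (isSet) {
    scaled <- SpectralSet(wavenumbers(x), scaled, classLabels(x),
                          classNames(x))
  }
  list(scaled = scaled, record = record)
}

#' @rdname scaleToUnitInterval
#' @param record a scaling record from [scaleToUnitInterval()]
#' @export
applyScaling <- function(x, record) {
  m <- checkMatrix(x)
  span <- record$max - record$min
  a <- ifelse(record$constant, 0, (record$hi - record$lo) / ifelse(span == 0, 1, span))
  out <- sweep(sweep(m, 2, record$min, "-"), 2, a, "*") + record$lo
  if (any(record$constant)) {
    out[, record$constant] <- (record$lo + record$hi) / 2
  }
  out
}

#' @rdname scaleToUnitInterval
#' @export
invertScaling <- function(x, record) {
  m <- checkMatrix(x)
  span <- record$max - record$min
  a <- ifelse(record$constant, 0, (record$hi - record$lo) / ifelse(span == 0, 1, span))
  out <- sweep(sweep(m, 2, record$lo, "-"), 2,
               ifelse(record$constant, 1, a), "/")
  out <- sweep(out, 2, record$min, "+")
  if (any(record$constant)) {
    out[, record$constant] <- rep(record$min[record$constant],
                                  each = nrow(m))
  }
  out
}
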