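#' Configuration for the synthetic FTIR spectrum generator
#'
#' Builds a validated configuration for [generateSpectra()]. The defaults
#' emulate the shape of a mid-infrared plant-tissue study: 13 classes, an
#' axis of 7157 points spanning 4000-550 cm^-1, and Gaussian absorption
#' bands at the canonical leaf-tissue positions (broad O-H stretch near
#' 3322 cm^-1, C-H stretches at 2924/2849, water and carbohydrate bands in
#' the fingerprint region, and the dominant C-O stretch near 1023 cm^-1).
#'
#' @param nClasses number of classes C (default 13).
#' @param nPerClass samples per class (default 24).
#' @param nPoints axis length P (default 7157).
#' @param wnMax,wnMin axis endpoints in cm^-1 (defaults 4000 and 550).
#' @param bandCenters Gaussian band centers, cm^-1.
#' @param bandWidths Gaussian sigma per band, cm^-1; the 3322 band is broad
#'   (sigma 120), fingerprint bands narrow (sigma 15-30).
#' @param baseAmplitudes base absorbance amplitude per band; largest at
#'   1023 cm^-1.
#' @param informativeBands indices into `bandCenters` whose amplitudes are
#'   class-dependent (default: all bands).
#' @param classEffectSize relative amplitude modulation between classes
#'   (default 0.5).
#' @param noiseSd i.i.d. Gaussian noise sd in absorbance units (default 0.02).
#' @param baselineOffset,baselineSlope ranges (length-2) of the per-sample
#'   linear baseline drift.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @return list of class `"SyntheticSpectraConfig"`.
#' @export
syntheticSpectraConfig <- function(nClasses = 13L,
                                   nPerClass = 24L,
                                   nPoints = 7157L,
                                   wnMax = 4000,
                                   wnMin = 550,
                                   bandCenters = c(3322, 2924, 2849, 1620,
                                                   1417, 1369, 1237, 1023),
                                   bandWidths = c(120, 20, 20, 30,
                                                  18, 15, 18, 25),
                                   baseAmplitudes = c(0.6, 0.35, 0.3, 0.5,
                                                      0.3, 0.28, 0.3, 1.0),
                                   informativeBands = seq_along(bandCenters),
                                   classEffectSize = 0.5,
                                   noiseSd = 0.02,
                                   baselineOffset = c(-0.05, 0.05),
                                   baselineSlope = c(-0.05, 0.05),
                                   seed = 1L) {
  cfg <- list(nClasses = as.integer(nClasses),
              nPerClass = as.integer(nPerClass),
              nPoints = as.integer(nPoints),
              wnMax = wnMax, wnMin = wnMin,
              bandCenters = bandCenters, bandWidths = bandWidths,
              baseAmplitudes = baseAmplitudes,
              informativeBands = as.integer(informativeBands),
              classEffectSize = classEffectSize,
              noiseSd = noiseSd,
              baselineOffset = baselineOffset,
              baselineSlope = baselineSlope,
              seed = as.integer(seed))
  if (cfg$nPoints < 2L) stop("nPoints must be >= 2")
  if (cfg$wnMax <= cfg$wnMin) stop("wnMax must exceed wnMin")
  nb <- length(cfg$bandCenters)
  if (length(cfg$bandWidths) != nb || length(cfg$baseAmplitudes) != nb) {
    stop("bandCenters, bandWidths and baseAmplitudes must have equal length")
  }
  if (length(cfg$informativeBands) &&
      !all(cfg$informativeBands %in% seq_len(nb))) {
    stop("informativeBands must index into bandCenters")
  }
  if (cfg$classEffectSize < 0) stop("classEffectSize must be >= 0")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  if (cfg$nClasses < 2L || cfg$nPerClass < 1L) {
    stop("need nClasses >= 2 and nPerClass >= 1")
  }
  if (!length(cfg$informativeBands) && cfg$classEffectSize > 0) {
    warning("classEffectSize > 0 with no informative bands: ",
            "classes will be indistinguishable")
  }
  structure(cfg, class = "SyntheticSpectraConfig")
}

#' Equally spaced descending wavenumber axis
#'
#' @param config a [syntheticSpectraConfig()] object.
#' @return numeric vector of `nPoints` equally spaced values from `wnMax`
#'   down to `wnMin`, inclusive.
#' @examples
#' axis <- makeAxis(syntheticSpectraConfig())
#' length(axis)  # 7157
#' range(axis)   # 550 4000
#' @export
makeAxis <- function(config) {
  if (config$nPoints < 2L) stop("nPoints must be >= 2")
  seq(config$wnMax, config$wnMin, length.out = config$nPoints)
}

#' Generate a synthetic multi-class FTIR-like dataset
#'
#' Each spectrum is a sum of Gaussian absorption bands plus a per-sample
#' linear baseline and i.i.d. Gaussian noise. For informative bands the
#' amplitude is `base * (1 + classEffectSize * delta[class, band])` where
#' `delta` is a fixed per-class pattern drawn once (uniform in \[-1, 1\])
#' from the seed, so classes differ only in the amplitudes of informative
#' bands. The ground truth marks every axis index within +/- 2 sigma of an
#' informative band center; gradient saliency spreads over a band, not a
#' single grid point, so selections are judged at band granularity.
#'
#' @param config a [syntheticSpectraConfig()] object.
#' @return list with `dataset` (a [SpectralSet-class]), `groundTruth`
#'   (sorted 1-based axis indices inside informative bands) and `config`.
#' @examples
#' sim <- generateSpectra(syntheticSpectraConfig(nPoints = 200,
#'                                               nClasses = 3,
#'                                               nPerClass = 5))
#' sim$dataset
#' @export
generateSpectra <- function(config) {
  stopifnot(inherits(config, "SyntheticSpectraConfig"))
  wn <- makeAxis(config)
  C <- config$nClasses
  N <- C * config$nPerClass
  P <- config$nPoints
  nb <- length(config$bandCenters)
  # Gaussian band profiles on the axis, one column per band
  profiles <- vapply(seq_len(nb), function(b) {
    exp(-(wn - config$bandCenters[b])^2 / (2 * config$bandWidths[b]^2))
  }, numeric(P))
  labels <- rep(seq_len(C) - 1L, each = config$nPerClass)
  t01 <- (config$wnMax - wn) / (config$wnMax - config$wnMin)  # 0 at wnMax
  withSeed(config$seed, {
    delta <- matrix(0, C, nb)
    if (length(config$informativeBands)) {
      delta[, config$informativeBands] <-
        matrix(runif(C * length(config$informativeBands), -1, 1),
               C, length(config$informativeBands))
    }
    amp <- matrix(rep(config$baseAmplitudes, each = C), C, nb)
    amp <- amp * (1 + config$classEffectSize * delta)
    X <- amp[labels + 1L, , drop = FALSE] %*% t(profiles)
    offs <- runif(N, config$baselineOffset[1], config$baselineOffset[2])
    slope <- runif(N, config$baselineSlope[1], config$baselineSlope[2])
    X <- X + outer(offs, rep(1, P)) + outer(slope, t01)
    if (config$noiseSd > 0) {
      X <- X + matrix(stats::rnorm(N * P, sd = config$noiseSd), N, P)
    }
  })
  truth <- integer(0)
  for (b in config$informativeBands) {
    truth <- c(truth, which(abs(wn - config$bandCenters[b]) <=
                              2 * config$bandWidths[b]))
  }
  list(dataset = SpectralSet(wn, X, labels),
       groundTruth = sort(unique(truth)),
       config = config)
}
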