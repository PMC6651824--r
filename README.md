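# ssaeSpectra

Classification of Fourier-transform infrared (FTIR) absorbance spectra with
**stacked sparse auto-encoders** (SSAE) and selection of informative
wavenumbers from the gradient of the supervised loss with respect to the
input spectrum — **guided-backward saliency** — together with the standard
chemometric baselines used to benchmark such selections.

## Who this is for

Chemometricians and plant scientists classifying mid-infrared spectra
(4000–550 cm⁻¹) of similar biological materials — cultivar or variety
identification being the canonical case — who want both a discriminant
model and a small, interpretable set of wavenumbers that carries the
discriminative information (e.g. for building cheap filter-based
instruments).

## The methods

* **Sparse auto-encoder layer**: encoder `h = f(W₁x + b₁)`, decoder
  `z = f(W₂h + b₂)` with the logistic sigmoid `f`, trained by gradient
  descent on

  `L = ½ Σᵢ ‖zᵢ − xᵢ‖² + β Σⱼ KL(ρ ‖ ρ̂ⱼ)`,

  where `ρ̂ⱼ` is the mean activation of hidden unit *j* and
  `KL(ρ‖ρ̂) = ρ ln(ρ/ρ̂) + (1−ρ) ln((1−ρ)/(1−ρ̂))` pulls activations toward
  the sparsity target `ρ`.
* **SSAE classifier**: greedy layerwise pretraining, decoders discarded, a
  softmax head `P(y=j|x) ∝ exp(θⱼᵀf)` attached, and the whole network
  fine-tuned on the penalised negative log-likelihood
  `J(θ) = −(1/m) Σᵢ Σⱼ 1{yᵢ=j} ln P(yᵢ=j|xᵢ;θ) + (λ/2)‖θ‖²`.
* **SSAE-GB selection**: `∂J/∂x` chained through softmax and every encoder
  layer, pooled over samples, normalised to max |value| = 1; local extrema
  with |value| > 0.5 are the selected wavenumbers.
* **Baselines**: Euclidean KNN (k searched 3–20), one-vs-one RBF-SVM
  (c, g grid-searched over powers of two, 2⁻⁸–2⁸), PCA-loading selection
  (max |loading| over the first 6 PCs), and CARS (Monte-Carlo PLS runs with
  an exponential-decay retention schedule and adaptive reweighted sampling,
  winner by minimum RMSECV) over a from-scratch SIMPLS core.
* **Synthetic generator**: 13-class FTIR-like spectra with Gaussian bands
  at 3322, 2924, 2849, 1620, 1417, 1369, 1237 and 1023 cm⁻¹, class-dependent
  amplitudes at planted positions, baseline drift and noise — so selection
  methods can be scored against known ground truth.

All of it is exposed through Bioconductor-style S4 classes
(`SpectralSet` extends `SummarizedExperiment`; `SSAEModel`,
`GuidedSaliency`, `SelectionResult`, `CVReport`).

## Worked example

```r
library(ssaeSpectra)

sim <- generateSpectra(syntheticSpectraConfig(nPoints = 1000,
                                              noiseSd = 0.01, seed = 1))
sim$dataset
#> SpectralSet: 312 samples x 1000 wavenumbers (4000.0..550.0 cm^-1)
#> 13 classes: class0(24) class1(24) ... class9(24)

fit <- trainSSAE(sim$dataset)              # scale, pretrain (64, 13), fine-tune
sal <- guidedBackward(fit$model, sim$dataset)
sel <- selectWavenumbers(sal, threshold = 0.5)
sel
#> SelectionResult [ssae-gb]: 15 wavenumbers (threshold/count 0.5)
#>   cm^-1: 2884.5, 2874.2, 2863.8, 2856.9, 2836.2, 2829.3, 2822.4, 2815.5 ...

selectionQuality(sel, sim$groundTruth, tolerance = 2)
#> precision 1.00  recall 0.50  (15 selected)

selectionFraction(15, 1000)
#> 1.5                    # percent of the axis retained

folds <- makeFolds(classLabels(sim$dataset), nFolds = 3, seed = 1)
tableReport(sim$dataset, "knn", folds, selection = sel)
#> CVReport for knn [perFold=4,3,3]
#>             fold1 fold2 fold3 mean
#> Calibration  98.6  98.6  97.1 98.1
#> Prediction   88.5  96.2  97.1 93.9
```

Every selected wavenumber lies inside a planted informative band
(precision 1.0), the selection keeps 1.5 % of the axis, and a KNN restricted
to those 15 wavenumbers still classifies held-out spectra at ~94 %.

A thin CLI over the same functions lives at
`inst/scripts/ssae-spectra-cli.R` (`simulate`, `train`, `select`,
`evaluate` subcommands).

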