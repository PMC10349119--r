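---
title: "Classifying SERS Raman spectra of genomic DNA: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SERS Raman spectra of genomic DNA: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanclass)
```

## The problem

Surface-enhanced Raman scattering (SERS) on silver-coated silicon nanowires
amplifies the vibrational fingerprint of genomic DNA deposited on the
substrate. Spectra collected from dried DNA drops carry two kinds of
diagnostic information: low-wavenumber (LW, 125.25--549.27 cm^-1) bands that
report the physico-chemical interaction of the molecules with the nanowires
(the Ag--N stretch near 234 cm^-1 and the Si substrate line near 514 cm^-1),
and high-wavenumber (HW, 2303.16--3399.83 cm^-1) CH~2~/CH~3~ stretching bands
near 2934 cm^-1 whose intensity is sensitive to DNA methylation. Comparing
two samples — healthy versus tumor, or two tumor subtypes — becomes a binary
classification problem on the matrix of spectra: `N` rows (spectra, target
label `W` of 1 for the first sample and 0 for the second) by `p` wavenumber
columns.

This package implements the complete analysis as a reusable pipeline: five
classifiers evaluated by stratified ten-fold cross-validated ROC--AUC,
preprocessing, two interpretability tools, unsupervised clustering, and a
synthetic spectra generator that stands in for measured maps (which are not
publicly available for this kind of study), so every stage is testable.

## Preprocessing

Stages run in a fixed order (`preprocess()` records it in its output):

1. **Background correction** (`background_correct()`): an order-3 polynomial
   baseline is estimated by iterated clipped least squares — after each fit,
   points above the current baseline are clipped down to it, so Raman bands do
   not drag the fit — and subtracted. Real instruments often emit spectra with
   this correction already applied; pass `background_order = NA` to skip.
   A plain single-pass fit is available (`iterative = FALSE`).
2. **Outlier rejection** (`remove_outliers()`): for each label group, the
   pointwise mean ± 3 SD envelope is formed and any spectrum with at least one
   point strictly outside is discarded. Boundary points count as inside.
   Group-wise envelopes are the default because the envelope is built around
   each sample's average spectrum; `pooled = TRUE` uses one envelope.
3. **Savitzky--Golay smoothing** (`sg_smooth()`): local least-squares
   polynomial fits applied as convolution coefficients. A symmetric window
   must be odd, so the conventional "90-point" setting maps to the default
   window of 91 points (polynomial order 3); an even request is rejected with
   a pointer to the nearest odd widths.

## The five classifiers

All models are fitted inside each cross-validation fold; nothing leaks from
the held-out fold. `cross_validate()` partitions spectra into ten
label-stratified folds (stratification guarantees the fold AUC is defined)
and reports the per-fold AUCs, their mean, and the standard error of that
mean.

- **LRA** — ridge-penalized logistic regression on a single feature, the
  global mean intensity of the region. The deliberately crude baseline
  model.
- **L2D** — nearest-mean rule with a tunable weight: compute the squared
  Euclidean distances `d1`, `d2` from a spectrum to the two class-mean
  spectra and assign class 1 iff `tau * d1 <= (1 - tau) * d2`. `tau = 0.5`
  is plain nearest-centroid; `fit_l2d()` selects `tau` on a 51-point grid by
  ten-fold CV AUC of the margin `(1 - tau) * d2 - tau * d1`, ties broken
  toward 0.5.
- **LRP** — ridge logistic regression on average-pooled features: the region
  is cut into non-overlapping, non-equispaced sub-domains (4 for LW, 3 for
  HW by default) and each contributes its mean intensity. The default cuts
  (`pooling_lw()`, `pooling_hw()`) isolate the Si-band cell 480--549 cm^-1
  and the CH cells 2700--3200 / 3200--3400 cm^-1; they are fully
  configurable, since any particular choice of interior boundaries is a
  modelling decision.
- **PCA** — ridge logistic regression on the scores of the leading principal
  components of the column-centered training matrix. Components are kept
  until 99.9% cumulative variance, capped at 5. Loading signs are fixed by
  making each component's largest-magnitude loading positive, so loading
  plots are reproducible. A decision threshold `lambda` on the predicted
  probability can be tuned with `tune_threshold()`; it is tuned on
  classification accuracy because ROC--AUC, the reported metric, is
  invariant to the cut.
- **CNN** — a fixed 1-D convolutional network: three blocks of
  [convolution (64 filters, kernel 3, valid, softplus) → max-pool 2 →
  dropout 0.25], then flatten, a 16-unit softplus layer, and a 1-unit
  sigmoid output. Training is mini-batch ADAM (batch 64, learning rate
  0.001) on binary cross-entropy, with raw intensities in — spectra are
  neither rescaled nor otherwise transformed.

The ridge penalty in all logistic fits is `shrinkage/2 * sum(beta^2)` on the
original-scale coefficients, intercept unpenalized, with `shrinkage = 1` by
default — read as a penalty strength. On count-scale features the
discriminative coefficients are tiny, so this penalty mainly guards against
divergence under perfect separation.

### CNN numerical choices

The fixed architecture leaves several details open; the package's choices
are:

- **Valid convolutions** (no padding): a purely convolutional stack with an
  explicit flatten suggests plainly shrinking feature maps. The per-stage
  lengths follow `L -> L - 2 -> floor(L / 2)`; `cnn_out_lengths()` and
  `cnn_param_count()` expose the arithmetic (50 593 parameters for the
  221-point LW window).
- **Dropout after each pooling layer.**
- **Epochs**: 50 by default with early stopping on a stratified 10%
  validation split (patience 10, best weights restored); both are
  configurable, and `validation_split = 0` disables early stopping.
- **Initialization**: weights are He-scaled Gaussian draws, and each layer
  additionally carries a fixed scalar scale constant calibrated once, at the
  start of training, on a label-mixed probe batch with dropout active, so
  that the layer's pre-activations have mean 0 / SD 1. Raw spectra sit at
  count scales (hundreds to thousands), orders of magnitude away from the
  unit scale standard initializations assume; without the calibration the
  softplus stack saturates into a constant-output network that gradient
  descent cannot leave. The constants are part of the initialization — they
  are not trained, and the data are never rescaled. The probe must contain
  both classes: calibrated on one class only, the deepest scale amplifies
  the between-class shift and saturates the output immediately.
- **Saliency**: vanilla gradients `d o / d X_j` are computed on the test
  set with dropout off, then mapped through the empirical CDF of the pooled
  set of all test-set derivatives (midranks for ties). Pooling over the
  whole test set is the default because the map is meant to be comparable
  across wavenumbers; a per-wavenumber CDF variant is available
  (`per_wavenumber = TRUE`). The summary is the per-wavenumber mean of the
  CDF values with a 95% normal interval (mean ± 1.96 SEM) across spectra.
  Gradients are exact: they match central finite differences to well below
  0.1% away from max-pool argmax switches.

## Interpretability

`permutation_importance()` scores each feature column as the model's test
ROC--AUC minus the mean AUC after shuffling that column (30 independent
shuffles by default). Shuffling breaks the feature--label association while
preserving the marginal distribution, so a large drop marks a feature the
discrimination relies on. Applied to the LRP features, it points at the
sub-domain carrying a discriminative band.

## Unsupervised clustering

`cluster_comparison()` standardizes each spectrum (population SD, so mean 0 /
SD 1 hold exactly), builds the pairwise cosine affinity — on standardized
spectra this equals the Pearson correlation of the raw spectra — and runs
two-way spectral clustering: negative affinities are clipped to zero
(normalized graph cuts assume non-negative weights), the symmetric normalized
Laplacian is formed, and k-means (10 seeded restarts) partitions the
two-dimensional spectral embedding. Agreement with the true labels is scored
by the Matthews correlation coefficient; since cluster indices carry no class
meaning, both orientations are evaluated and the larger MCC reported, with 0
returned when a marginal is empty.

One structural caveat: after per-spectrum standardization, a purely
multiplicative change of a *single* band in a region where that band is the
only feature leaves the spectrum's shape unchanged, and cosine affinity
cannot see it. Separability by this route requires the class effect to alter
the *relative* band pattern — which real multi-band spectra do.

## The synthetic generator

`generate_dataset()` draws two classes of spectra as
`baseline + sum(bands) + noise`:

- **Axis**: 1700 uniform points over 125.25--3399.83 cm^-1. With this grid
  the LW window holds exactly 221 points and the HW window 570, and the
  spacing (~1.9274 cm^-1) matches the value implied by the LW endpoints and
  count.
- **Bands** (`default_peaks()`): Lorentzian lines (Gaussian selectable) at
  234 (Ag--N), 514 (Si), 670/785/1003/1095 (DNA bases and backbone), and a
  high-wavenumber complex at 2850, 2934 and 3250 cm^-1. Class effects are
  multiplicative on band amplitude (`class_delta`), matching the picture of
  class-dependent band intensities; `delta_si` and `delta_ch` dial the two
  diagnostically meaningful effects.
- **Baseline**: a cubic polynomial on the unit-scaled axis, shared by both
  classes, emulating residual fluorescence.
- **Noise**: Gaussian with marginal SD `noise_sd`, correlated along the axis
  (squared-exponential kernel, default length 100 cm^-1) with a 30% white
  component. The correlation matters: with independent noise at p = 1700,
  the ±3 SD any-point decision surface would flag nearly every spectrum
  (about 4.6 expected exceedances each), while smooth noise concentrates
  exceedances in few spectra — the regime in which the filter removes only
  gross outliers, as it does on real maps. `noise_correlation = 0` recovers
  strictly independent noise.
- **Outliers**: a seeded Bernoulli fraction (default 1%) of spectra receive
  a single-point spike of 12 noise-SDs — guaranteed violations of the
  decision surface, for testing the filter.

What the generator does *not* emulate: spectrum-to-spectrum SERS enhancement
variability, spatial (drop-geometry) structure, wavenumber miscalibration,
cosmic rays, or any physical enhancement model. Tests passing on this
generator therefore certify the statistical machinery — not instrument
robustness on real maps.

## Problem sizes used by the test suite

The package's checks run the full machinery at reduced sizes chosen to keep
the suite fast while leaving the tested properties size-invariant:

- null calibration: 400 spectra/class for the four linear models (both
  regions, 5 seeds), 150/class and 10 epochs for the CNN (5 seeds),
  500/class for clustering; across-seed mean AUC must lie in [0.4, 0.6] and
  mean MCC in [-0.1, 0.1];
- signal recovery: 100 spectra/class through the entire pipeline
  (`run_comparison()`, 10-fold CV, CNN 10 epochs) with a CH-band effect of
  1.5 or an Si-band effect of 2.0; all five methods must reach AUC 0.95 on
  the affected region while the global methods stay at or below 0.7
  elsewhere;
- localization: 20 seeded runs for permutation importance and 10 for
  saliency, requiring at least 90% localization to the injected band;
- clustering: a CH-band effect of 2.0 ("strongly separated") must give
  MCC at least 0.9 on every one of 5 seeds.

`scripts/acceptance.R` recomputes the same quantities from scratch under a
caller-supplied master seed.

## Known limitations

- The CNN trains on one CPU; at full study sizes (2000 spectra/class) a
  ten-fold CV is computationally heavy, and the scaled-down defaults above
  are the tested regime.
- The spectral-clustering embedding uses the dense eigendecomposition of the
  N × N Laplacian; `run_comparison()` caps the clustering stage at 1000
  spectra (seeded stratified subsample) for that reason.
- Thresholds (`tau`, `lambda`) are tuned on grids of 51 points; finer grids
  cost proportionally more CV passes.
- `read_dataset()` expects the wide CSV/TSV layout with a label column; no
  vendor binary formats.
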