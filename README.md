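# ramanclass

Classification of surface-enhanced Raman (SERS) spectra of genomic DNA, for
discriminating healthy from tumor samples and tumor subtypes from one
another.

SERS substrates of Ag-coated silicon nanowires amplify the Raman fingerprint
of DNA dropped onto them. Two spectral windows carry the diagnostic signal:
the low-wavenumber window **LW** (125.25–549.27 cm⁻¹), with bands from the
DNA–nanowire interaction (Ag–N stretch ≈ 234 cm⁻¹, Si line ≈ 514 cm⁻¹), and
the high-wavenumber window **HW** (2303.16–3399.83 cm⁻¹), with CH₂/CH₃
stretching bands (≈ 2934 cm⁻¹) sensitive to DNA methylation. Given `N`
spectra with binary labels `W` (first vs. second sample), the package runs
five classifiers, each scored by stratified ten-fold cross-validated
ROC–AUC:

| method | model |
|---|---|
| LRA | ridge logistic regression on the region's global mean intensity |
| L2D | weighted nearest-mean rule: class 1 iff τ·d¹ ≤ (1−τ)·d², with d^k the squared ℓ² distance to the class-k mean spectrum and τ tuned by CV |
| LRP | ridge logistic regression on average-pooled sub-band means (4 cells on LW, 3 on HW) |
| PCA | ridge logistic regression on the leading principal-component scores (≥ 99.9 % cumulative variance, ≤ 5 components) |
| CNN | fixed 1-D convolutional net: 3 × [conv(64 × 3, softplus) → max-pool 2 → dropout 0.25] → dense 16 → sigmoid, ADAM on binary cross-entropy, raw intensities in |

Around the classifiers: preprocessing (iterative order-3 polynomial
background correction, pointwise mean ± 3 SD outlier rejection,
Savitzky–Golay smoothing, in that order), permutation importance for the
pooled model, vanilla-gradient saliency maps (empirical-CDF scaled) for the
network, and unsupervised two-way spectral clustering on the cosine affinity
of standardized spectra, scored by the Matthews correlation coefficient
(MCC). A synthetic generator produces SERS-like two-class datasets —
Lorentzian bands on a fluorescence baseline with axis-correlated noise and
injected gross outliers — so the whole pipeline is testable without measured
maps.

## Worked example

Two synthetic "tumor subtypes" whose only difference is a 1.5× stronger CH
band — a methylation-like, HW-only effect:

```r
library(ramanclass)

cfg <- synthetic_config(n_per_class = 100,
                        peaks = default_peaks(delta_ch = 1.5),
                        seed = 42)
report <- run_comparison(cfg, seed = 1, folds = 10, cnn_epochs = 10,
                         cnn_validation_split = 0,
                         case = "subtype A vs. subtype B")
make_roc_table(report)
#>                      case region  LRA  L2D  LRP  PCA  CNN
#> 1 subtype A vs. subtype B     LW 0.52 0.38 0.47 0.41 0.53
#> 2 subtype A vs. subtype B     HW 1.00 1.00 1.00 1.00 1.00
```

The pattern is the scientifically meaningful result: every method separates
the classes perfectly on HW, where the injected band effect lives, while all
of them hover at chance on LW, which carries no class signal. The
unsupervised route sees the same structure —

```r
report$mcc
#> $LW
#> [1] 0.01107655
#> $HW
#> [1] 0.8481712
```

— and permutation importance localizes the HW discrimination to the pooled
cell containing the 2934 cm⁻¹ band (cells 2303–2700 / 2700–3200 /
3200–3400 cm⁻¹):

```r
round(report$importance$HW$scores, 3)
#> [1] 0.000 0.523 0.000
```

An AUC drop of 0.52 after shuffling the middle cell means the model's
discrimination collapses to chance without it; the flanking cells contribute
nothing.

A command-line wrapper for the same workflow lives at
`inst/cli/ramanclass.R` (`simulate` and `run` subcommands, YAML configs).

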