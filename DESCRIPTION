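Package: ramanclass
Title: Classification of SERS Raman Spectra of Genomic DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pairwise classification of surface-enhanced Raman
    (SERS) spectra of genomic DNA, as used to discriminate healthy versus
    tumor samples and tumor subtypes. Provides preprocessing (iterative
    polynomial background correction, pointwise mean +/- k SD outlier
    rejection, Savitzky-Golay smoothing), five classifiers (logistic
    regression on the global mean, a tau-weighted nearest-mean l2 rule,
    logistic regression on average-pooled sub-bands, logistic regression on
    principal components, and a fixed 1-D convolutional neural network),
    ten-fold cross-validated ROC-AUC evaluation, permutation importance and
    vanilla-gradient saliency maps for interpretability, unsupervised
    spectral clustering with a cosine affinity scored by Matthews
    correlation, and a synthetic SERS-like spectra generator for testing
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
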