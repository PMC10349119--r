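# Small, fast synthetic configurations shared across test files.

# short axis holding both analysis windows at full resolution is too big for
# unit tests; this one keeps ~60 points around a single band
tiny_axis_config <- function(...) {
  synthetic_config(axis_start = 2904, axis_stop = 2964, axis_points = 61,
                   peaks = list(peak_spec(2934, 10, 100)),
                   baseline_coeffs = 0, noise_sd = 0, outlier_rate = 0,
                   n_per_class = 2, ...)
}

# two-class set with a class effect on one band, flat baseline, modest noise
small_effect_config <- function(n_per_class = 50, delta = 1.5, noise_sd = 5,
                                seed = 1L) {
  synthetic_config(axis_start = 100, axis_stop = 700, axis_points = 120,
                   peaks = list(peak_spec(250, 15, 80),
                                peak_spec(514, 15, 80, class_delta = delta)),
                   baseline_coeffs = c(20, 10), noise_sd = noise_sd,
                   outlier_rate = 0, n_per_class = n_per_class, seed = seed)
}

# brute-force ROC-AUC by pair counting (independent oracle)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
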