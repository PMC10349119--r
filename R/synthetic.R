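#' Band definition for the synthetic spectra generator
#'
#' One vibrational band, modelled as a Lorentzian (default) or Gaussian line.
#' `class_delta` is a multiplicative effect on the amplitude applied to
#' class-1 spectra only: 1 means no class difference at this band.
#'
#' @param center Band center, cm^-1.
#' @param width Half-width at half-maximum (Lorentzian) or SD (Gaussian), cm^-1.
#' @param amplitude Peak amplitude at the center, counts; >= 0.
#' @param class_delta Multiplicative amplitude factor for class 1; >= 0.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width, amplitude, class_delta = 1) {
  if (width <= 0) stop("invalid peak: width must be > 0")
  if (amplitude < 0) stop("invalid peak: amplitude must be >= 0")
  if (class_delta < 0) stop("invalid peak: class_delta must be >= 0")
  structure(list(center = center, width = width, amplitude = amplitude,
                 class_delta = class_delta), class = "peak_spec")
}

#' Default band set emulating SERS spectra of DNA on Ag-coated nanowires
#'
#' Bands at the positions seen in such measurements: the Ag-N stretch near
#' 234 cm^-1, the Si substrate line near 514 cm^-1, DNA base/backbone bands
#' between 600 and 1200 cm^-1, and the high-wavenumber stretching complex —
#' CH2 near 2850 cm^-1, the dominant CH2/CH3 band near 2934 cm^-1, and a
#' broad OH/NH shoulder near 3250 cm^-1.
#'
#' @param delta_si Class effect on the 514 cm^-1 Si band (surface-coverage
#'   differences between classes).
#' @param delta_ch Class effect on the 2934 cm^-1 CH band (methylation-degree
#'   differences).
#' @return List of [peak_spec()] objects.
#' @export
default_peaks <- function(delta_si = 1, delta_ch = 1) {
  list(peak_spec(234,  22, 800),
       peak_spec(514,  14, 600, class_delta = delta_si),
       peak_spec(670,  18, 250),
       peak_spec(785,  16, 380),
       peak_spec(1003, 10, 320),
       peak_spec(1095, 18, 280),
       peak_spec(2850, 20, 350),
       peak_spec(2934, 40, 1000, class_delta = delta_ch),
       peak_spec(3250, 70, 250))
}

#' Configuration for the synthetic SERS-like spectra generator
#'
#' Defaults mirror the acquisition design the analysis assumes: a uniform
#' 1700-point axis from 125.25 to 3399.83 cm^-1 (so the low-wavenumber window
#' 125.25-549.27 cm^-1 holds 221 points and the high-wavenumber window
#' 2303.16-3399.83 cm^-1 holds 570), 2000 spectra per class, a smooth cubic
#' fluorescence baseline, additive Gaussian noise correlated along the axis,
#' and a small fraction of gross outliers injected as single-point spikes.
#'
#' @param axis_start,axis_stop Axis endpoints, cm^-1.
#' @param axis_points Number of axis points (>= 2).
#' @param peaks List of [peak_spec()] objects.
#' @param baseline_coeffs Polynomial coefficients (intercept first) of the
#'   fluorescence baseline, evaluated on a unit-scaled axis.
#' @param noise_sd Marginal SD of the additive Gaussian noise, counts.
#' @param noise_correlation Correlation length of the noise along the axis in
#'   cm^-1 (squared-exponential kernel; default 100). Raman map noise is
#'   smooth across neighbouring wavenumbers — uncorrelated noise at realistic
#'   point counts would make the pointwise mean +/- 3 SD outlier surface
#'   reject nearly every spectrum. Set 0 for strictly independent noise.
#' @param noise_white_frac Fraction (in SD) of the noise budget left
#'   uncorrelated (default 0.3).
#' @param outlier_rate Fraction of spectra receiving a gross spike, in [0, 1).
#' @param outlier_magnitude Spike height in multiples of `noise_sd`.
#' @param n_per_class Spectra per class (>= 1).
#' @param profile `"lorentzian"` (typical Raman line shape) or `"gaussian"`.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(axis_start = 125.25, axis_stop = 3399.83,
                             axis_points = 1700,
                             peaks = default_peaks(),
                             baseline_coeffs = c(400, 250, -180, 60),
                             noise_sd = 30,
                             noise_correlation = 100,
                             noise_white_frac = 0.3,
                             outlier_rate = 0.01,
                             outlier_magnitude = 12,
                             n_per_class = 2000,
                             profile = c("lorentzian", "gaussian"),
                             seed = 1L) {
  profile <- match.arg(profile)
  if (axis_points < 2) stop("invalid config: axis_points must be >= 2")
  if (axis_stop <= axis_start) stop("invalid config: axis_stop must exceed axis_start")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("invalid config: outlier_rate must be in [0, 1)")
  if (n_per_class < 1) stop("invalid config: n_per_class must be >= 1")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (noise_correlation < 0) stop("invalid config: noise_correlation must be >= 0")
  if (noise_white_frac < 0 || noise_white_frac > 1)
    stop("invalid config: noise_white_frac must be in [0, 1]")
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(axis_start = axis_start, axis_stop = axis_stop,
                 axis_points = as.integer(axis_points), peaks = peaks,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd,
                 noise_correlation = noise_correlation,
                 noise_white_frac = noise_white_frac,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 n_per_class = as.integer(n_per_class),
                 profile = profile, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Uniform wavenumber axis
#'
#' @param start,stop Endpoints in cm^-1, `stop > start`.
#' @param n Number of points, >= 2.
#' @return Strictly increasing, uniformly spaced vector with first element
#'   `start` and last `stop`.
#' @examples
#' generate_axis(0, 1, 2)
#' diff(generate_axis(125.25, 549.27, 221))[1]  # 424.02 / 220
#' @export
generate_axis <- function(start, stop, n) {
  if (n < 2) stop("invalid config: need n >= 2 axis points")
  if (stop <= start) stop("invalid config: need stop > start")
  seq(start, stop, length.out = n)
}

line_profile <- function(axis, peak, profile) {
  if (profile == "lorentzian") {
    peak$amplitude / (1 + ((axis - peak$center) / peak$width)^2)
  } else {
    peak$amplitude * exp(-0.5 * ((axis - peak$center) / peak$width)^2)
  }
}

# Noise-free signal shared by all spectra of one class: baseline polynomial
# (on the axis rescaled to [0,1] for conditioning) plus the band sum, with
# each band's amplitude multiplied by class_delta for class 1.
signal_template <- function(config, class_label, axis) {
  u <- (axis - config$axis_start) / (config$axis_stop - config$axis_start)
  base <- rep(0, length(axis))
  for (j in seq_along(config$baseline_coeffs))
    base <- base + config$baseline_coeffs[j] * u^(j - 1)
  for (pk in config$peaks) {
    eff <- if (class_label == 1L) pk$class_delta else 1
    scaled <- pk
    scaled$amplitude <- pk$amplitude * eff
    base <- base + line_profile(axis, scaled, config$profile)
  }
  base
}

# n draws of axis-correlated Gaussian noise with marginal SD `sd`:
# sqrt(1 - w^2) * GP(squared-exponential, length corr_cm) + w * white.
# Returns an n x p matrix.
correlated_noise <- function(n, axis, sd, corr_cm, white_frac) {
  p <- length(axis)
  if (sd == 0) return(matrix(0, n, p))
  white <- matrix(stats::rnorm(n * p), n, p)
  if (corr_cm == 0) return(white * sd)
  K <- exp(-outer(axis, axis, "-")^2 / (2 * corr_cm^2))
  L <- chol(K + 1e-8 * diag(p))
  smooth <- matrix(stats::rnorm(n * p), n, p) %*% L
  (sqrt(1 - white_frac^2) * smooth + white_frac * white) * sd
}

#' Draw one synthetic spectrum
#'
#' Deterministic signal (baseline + bands, with class effects for class 1)
#' plus axis-correlated Gaussian noise, drawn from the current RNG state.
#'
#' @param config A [synthetic_config()].
#' @param class_label 0 or 1.
#' @return Intensity vector of length `config$axis_points`.
#' @export
generate_spectrum <- function(config, class_label) {
  stopifnot(inherits(config, "synthetic_config"), class_label %in% c(0, 1))
  axis <- generate_axis(config$axis_start, config$axis_stop, config$axis_points)
  signal_template(config, as.integer(class_label), axis) +
    drop(correlated_noise(1, axis, config$noise_sd, config$noise_correlation,
                          config$noise_white_frac))
}

#' Generate a two-class synthetic dataset
#'
#' Draws `n_per_class` spectra per class, then spikes a seeded Bernoulli
#' fraction `outlier_rate` of rows at one random position by
#' `outlier_magnitude * noise_sd`, emulating the gross outliers the
#' mean +/- 3 SD decision surface is meant to reject. Label 1 rows come
#' first. Identical configs (including `seed`) give bit-identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return A [spectral_dataset()]; attribute `"outlier_rows"` holds the
#'   indices of spiked rows.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  axis <- generate_axis(config$axis_start, config$axis_stop, config$axis_points)
  n <- config$n_per_class
  p <- config$axis_points
  tpl1 <- signal_template(config, 1L, axis)
  tpl0 <- signal_template(config, 0L, axis)
  x <- rbind(matrix(tpl1, n, p, byrow = TRUE),
             matrix(tpl0, n, p, byrow = TRUE))
  if (config$noise_sd > 0)
    x <- x + correlated_noise(2 * n, axis, config$noise_sd,
                              config$noise_correlation,
                              config$noise_white_frac)
  labels <- rep(c(1L, 0L), each = n)
  spiked <- which(stats::runif(2 * n) < config$outlier_rate)
  for (i in spiked) {
    pos <- sample.int(p, 1)
    x[i, pos] <- x[i, pos] + config$outlier_magnitude * config$noise_sd
  }
  ds <- spectral_dataset(axis, x, labels)
  attr(ds, "outlier_rows") <- spiked
  ds
}
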