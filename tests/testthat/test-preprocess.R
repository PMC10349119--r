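test_that("background_correct removes polynomial baselines exactly", {
  u <- seq(0, 1, length.out = 200)
  cubic <- 5 + 3 * u - 8 * u^2 + 2 * u^3
  res <- background_correct(cubic, order = 3)
  expect_lt(max(abs(res)), 1e-6 * diff(range(cubic)))

  expect_equal(background_correct(rep(4.2, 50), order = 0), rep(0, 50),
               tolerance = 1e-10)
  expect_error(background_correct(1:3, order = 3), "invalid config")
})

test_that("background_correct recovers a narrow band riding a cubic baseline", {
  ax <- seq_len(500)
  baseline <- 100 + 0.5 * ax - 1e-3 * ax^2 + 8e-7 * ax^3
  peak <- 50 / (1 + ((ax - 250) / 8)^2)   # Lorentzian, amplitude 50
  corrected <- background_correct(baseline + peak, order = 3)
  expect_equal(corrected[250], 50, tolerance = 0.05 * 50)
})

test_that("remove_outliers discards exactly the spectra leaving the k-SD band", {
  # degenerate dispersion: identical spectra, everything on the surface
  ds <- spectral_dataset(1:5, matrix(1, 10, 5), rep(c(0, 1), each = 5))
  expect_length(remove_outliers(ds, 3)$removed, 0)

  # one gross spike among noise spectra
  set.seed(7)
  x <- matrix(rnorm(201 * 30), 201, 30)
  x[77, 12] <- x[77, 12] + 10
  ds2 <- spectral_dataset(1:30, x, rep(1, 201) * c(rep(0, 100), rep(1, 101)))
  out <- remove_outliers(ds2, 3)
  expect_true(77 %in% out$removed)

  # brute-force agreement, per label group
  flagged <- integer(0)
  for (lab in 0:1) {
    idx <- which(ds2$labels == lab)
    g <- ds2$intensities[idx, ]
    mu <- colMeans(g)
    sdv <- apply(g, 2, sd)
    bad <- idx[apply(g, 1, function(r) any(r < mu - 3 * sdv | r > mu + 3 * sdv))]
    flagged <- c(flagged, bad)
  }
  expect_identical(out$removed, sort(flagged))

  # infinitely wide surface removes nothing
  expect_length(remove_outliers(ds2, 1e9)$removed, 0)

  # a group with fewer than two members cannot define a surface
  ds3 <- spectral_dataset(1:3, matrix(rnorm(9), 3), c(1, 0, 0))
  expect_error(remove_outliers(ds3), "insufficient data")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  # constants and ramps are fixed points up to machine-level error
  expect_equal(sg_smooth(rep(3, 200), window = 91, polyorder = 3),
               rep(3, 200), tolerance = 1e-9)
  ramp <- seq(0, 10, length.out = 200)
  expect_equal(sg_smooth(ramp, window = 91, polyorder = 3), ramp,
               tolerance = 1e-9)

  # interior variance of filtered white noise drops below 0.1
  set.seed(1)
  noise <- matrix(rnorm(50 * 300), 50, 300)
  sm <- t(apply(noise, 1, sg_smooth, window = 91, polyorder = 3))
  interior <- sm[, 46:255]
  expect_lt(mean(apply(interior, 2, var)), 0.1)

  # even windows are rejected with a pointer to the nearest odd widths
  expect_error(sg_smooth(rnorm(100), window = 90), "91")
  expect_error(sg_smooth(rnorm(100), window = 5, polyorder = 5), "polyorder")
  expect_error(sg_smooth(rnorm(50), window = 91), "length")
})

test_that("smoothing commutes with adding a global constant", {
  set.seed(2)
  x <- rnorm(150)
  expect_equal(sg_smooth(x + 5, window = 31, polyorder = 3),
               sg_smooth(x, window = 31, polyorder = 3) + 5,
               tolerance = 1e-10)
})

test_that("preprocess runs background -> outliers -> smoothing in order", {
  cfg <- small_effect_config(n_per_class = 20, noise_sd = 2)
  cfg$outlier_rate <- 0.1
  cfg$outlier_magnitude <- 15
  ds <- generate_dataset(cfg)
  out <- preprocess(ds, sg_window = 31)
  expect_identical(out$stages, c("background", "outliers", "smooth"))
  expect_true(all(attr(ds, "outlier_rows") %in% out$removed))
  expect_equal(nrow(out$dataset$intensities),
               nrow(ds$intensities) - length(out$removed))

  skipped <- preprocess(ds, background_order = NA, sg_window = 31)
  expect_identical(skipped$stages, c("outliers", "smooth"))
})
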