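test_that("layer-length arithmetic and parameter count follow the fixed architecture", {
  # worked example for the 221-point low-wavenumber window
  expect_equal(cnn_out_lengths(221), c(219, 109, 107, 53, 51, 25))
  expect_equal(cnn_param_count(221), 50593)

  # brute-force oracle over a sample of admissible lengths
  oracle_lengths <- function(n) {
    out <- integer(0)
    for (b in 1:3) {
      n <- n - 2            # valid convolution, kernel 3
      out <- c(out, n)
      n <- floor(n / 2)     # max-pool 2
      out <- c(out, n)
    }
    out
  }
  for (n in c(30:40, 221, 570, seq(45, 1200, by = 37))) {
    expect_equal(cnn_out_lengths(n), oracle_lengths(n))
    flat <- oracle_lengths(n)[6] * 64
    expect_equal(cnn_param_count(n),
                 (3 * 64 + 64) + 2 * (64 * 3 * 64 + 64) +
                   (flat * 16 + 16) + (16 + 1))
  }

  expect_error(build_cnn(20), "too short")
})

test_that("untrained network outputs probabilities strictly inside (0, 1)", {
  m <- build_cnn(64, seed = 5)
  X <- matrix(rnorm(10 * 64, sd = 100), 10, 64)
  p <- predict_cnn(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_length(p, 10)
})

test_that("training is deterministic given seeds and learns a separable pair", {
  cfg <- small_effect_config(n_per_class = 60, delta = 1.8, noise_sd = 5)
  ds <- generate_dataset(cfg)
  fit1 <- train_cnn(build_cnn(120, seed = 1), ds$intensities, ds$labels,
                    epochs = 8, validation_split = 0, seed = 2)
  fit2 <- train_cnn(build_cnn(120, seed = 1), ds$intensities, ds$labels,
                    epochs = 8, validation_split = 0, seed = 2)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$scales, fit2$scales)
  expect_length(fit1$loss_trace, 8)

  auc <- roc_auc(predict_cnn(fit1, ds$intensities), ds$labels)
  expect_gte(auc, 0.95)

  expect_error(train_cnn(build_cnn(64), matrix(1, 4, 32), c(0, 1, 0, 1)),
               "shape error")
  expect_error(train_cnn(build_cnn(120), ds$intensities, rep(1, 120)),
               "both labels")
})

test_that("vanilla gradients match central finite differences", {
  cfg <- small_effect_config(n_per_class = 30, delta = 1.6, noise_sd = 5)
  ds <- generate_dataset(cfg)
  m <- train_cnn(build_cnn(120, seed = 3), ds$intensities, ds$labels,
                 epochs = 3, validation_split = 0, seed = 4)
  X <- ds$intensities[1:5, , drop = FALSE]
  g <- cnn_input_gradients(m, X)
  set.seed(5)
  for (i in 1:5) {
    for (j in sample(120, 4)) {
      e <- numeric(120); e[j] <- 1e-3   # small enough not to cross pool kinks
      fd <- (predict_cnn(m, matrix(X[i, ] + e, 1)) -
             predict_cnn(m, matrix(X[i, ] - e, 1))) / 2e-3
      denom <- max(abs(fd), 1e-8)
      expect_lt(abs(g[i, j] - fd) / denom, 1e-3)
    }
  }
})

test_that("saliency CDF transform is uniform on [0, 1] and flat for constant gradients", {
  cfg <- small_effect_config(n_per_class = 30, delta = 1.6, noise_sd = 5)
  ds <- generate_dataset(cfg)
  m <- train_cnn(build_cnn(120, seed = 6), ds$intensities, ds$labels,
                 epochs = 3, validation_split = 0, seed = 7)
  sal <- vanilla_gradient_saliency(m, ds$intensities[1:20, ])
  expect_equal(dim(sal$cdf_values), c(20, 120))
  expect_true(all(sal$cdf_values >= 0 & sal$cdf_values <= 1))
  # pooled ranks are uniform by construction
  expect_equal(mean(sal$cdf_values), (20 * 120 + 1) / (2 * 20 * 120))
  expect_equal(nrow(sal$summary), 120)
  expect_true(all(sal$summary$lo95 <= sal$summary$mean &
                  sal$summary$mean <= sal$summary$hi95))

  # all-zero weights: constant derivative field, every CDF value tied at ~0.5
  m0 <- build_cnn(120)
  m0$params <- lapply(m0$params, function(p) p * 0)
  m0$trained <- TRUE
  sal0 <- vanilla_gradient_saliency(m0, ds$intensities[1:5, ])
  expect_equal(length(unique(c(sal0$cdf_values))), 1)
  n_pool <- 5 * 120
  expect_equal(sal0$cdf_values[1], (n_pool + 1) / (2 * n_pool))  # midrank tie

  expect_error(vanilla_gradient_saliency(m, ds$intensities[0, , drop = FALSE]),
               "insufficient data")
})

test_that("early stopping halts on a stalled validation loss", {
  cfg <- small_effect_config(n_per_class = 40, delta = 2, noise_sd = 2)
  ds <- generate_dataset(cfg)
  m <- train_cnn(build_cnn(120, seed = 8), ds$intensities, ds$labels,
                 epochs = 40, validation_split = 0.2, patience = 3, seed = 9)
  expect_lte(m$epochs_run, 40)
  expect_gte(m$epochs_run, 3)
})
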