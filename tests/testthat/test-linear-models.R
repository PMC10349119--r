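test_that("class_means averages each label group columnwise", {
  ds <- spectral_dataset(1:2, rbind(c(1, 2), c(1, 2)), c(1, 1, 0)[1:2])
  # two identical label-1 rows -> their common value; build a mixed set
  ds <- spectral_dataset(1:2, rbind(c(0, 0), c(2, 2), c(5, 7)), c(1, 1, 0))
  m <- class_means(ds)
  expect_equal(m$h1, c(1, 1))
  expect_equal(m$h2, c(5, 7))

  set.seed(3)
  x <- matrix(rnorm(500), 50, 10)
  lab <- rep(c(1, 0), 25)
  ds2 <- spectral_dataset(1:10, x, lab)
  m2 <- class_means(ds2)
  expect_equal(m2$h1, colMeans(x[lab == 1, ]))
  expect_equal(m2$h2, colMeans(x[lab == 0, ]))

  expect_error(class_means(spectral_dataset(1:2, x[1:3, 1:2], c(1, 1, 1))),
               "both labels")
})

test_that("l2_distance_sq is the squared euclidean distance, no square root", {
  expect_equal(l2_distance_sq(c(1, 2), c(0, 0)), 5)
  expect_equal(l2_distance_sq(3, -1), 16)
  expect_equal(l2_distance_sq(c(1, 2), c(1, 2)), 0)
  expect_error(l2_distance_sq(1:3, 1:2), "shape error")
})

test_that("l2d_classify implements the tau-weighted nearest-mean rule", {
  means <- list(h1 = c(0, 0), h2 = c(1, 2 - sqrt(3)))
  # x = (1, 2): d1 = 5, d2 = 3
  x <- c(1, 2)
  expect_equal(l2d_classify(x, list(means = means, tau = 0.5)), 0L)
  expect_equal(l2d_classify(x, list(means = means, tau = 0)), 1L)
  expect_equal(l2d_classify(means$h1, list(means = means, tau = 0.5)), 1L)

  # tau = 0.5 is exactly nearest-centroid (brute force over random cases)
  set.seed(11)
  h1 <- rnorm(8); h2 <- rnorm(8)
  model <- list(means = list(h1 = h1, h2 = h2), tau = 0.5)
  X <- matrix(rnorm(200 * 8), 200, 8)
  brute <- apply(X, 1, function(r)
    as.integer(sum((r - h1)^2) <= sum((r - h2)^2)))
  expect_identical(l2d_classify(X, model), brute)
})

test_that("fit_l2d tunes tau by CV AUC with ties toward 0.5", {
  cfg <- small_effect_config(n_per_class = 40, delta = 1.6, noise_sd = 5)
  ds <- generate_dataset(cfg)
  fit <- fit_l2d(ds, tau_grid = 0.5)
  expect_equal(fit$tau, 0.5)

  # symmetric classes: the CV objective is symmetric around 0.5
  fit2 <- fit_l2d(ds, seed = 4)
  expect_gte(fit2$tau, 0.3)
  expect_lte(fit2$tau, 0.7)
  expect_error(fit_l2d(ds, tau_grid = numeric(0)), "empty tau grid")
  expect_error(fit_l2d(ds, tau_grid = c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("average_pooling means each sub-domain, reducing to the global mean for one bin", {
  expect_equal(global_mean_feature(c(1, 2, 3)), 2)
  expect_equal(global_mean_feature(rep(7, 5)), 7)

  axis <- c(1, 2, 3, 4)
  sch <- pooling_scheme(c(1, 2, 4))
  expect_equal(average_pooling(c(1, 2, 3, 4), sch, axis), c(1.5, 3.5))

  const <- rep(4.5, 4)
  expect_equal(average_pooling(const, sch, axis), c(4.5, 4.5))

  all_bin <- pooling_scheme(c(1, 4))
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(average_pooling(X, all_bin, axis),
               matrix(global_mean_feature(X), ncol = 1))

  expect_error(average_pooling(c(1, 2), pooling_scheme(c(0, 0.5, 2)), c(1, 2)),
               "invalid scheme")
  expect_error(pooling_scheme(c(3, 2)), "increasing")
})

test_that("default pooling schemes cover their regions with 4 and 3 cells", {
  ds <- generate_dataset(synthetic_config(n_per_class = 2, noise_sd = 0,
                                          outlier_rate = 0))
  lw <- select_region(ds, region_lw())
  hw <- select_region(ds, region_hw())
  flw <- average_pooling(lw$intensities, pooling_lw(), lw$wavenumbers)
  fhw <- average_pooling(hw$intensities, pooling_hw(), hw$wavenumbers)
  expect_equal(ncol(flw), 4)
  expect_equal(ncol(fhw), 3)
})

test_that("ridge logistic regression matches Eq.-style predictions and stays finite", {
  # zero coefficients predict exactly 1/2; an intercept of ln 3 predicts 3/4
  expect_equal(predict_logistic(list(beta0 = 0, betas = 0), 5), 0.5)
  expect_equal(predict_logistic(list(beta0 = log(3), betas = 0), -2), 0.75)

  # perfectly separable single feature: the penalty keeps the fit finite
  f <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(f, y, shrinkage = 1)
  expect_true(is.finite(fit$betas))
  expect_true(fit$converged)

  # near-zero penalty agrees with glm's maximum likelihood fit
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  yy <- rbinom(100, 1, plogis(0.3 + X %*% c(1, -0.5, 0)))
  ours <- fit_logistic(X, yy, shrinkage = 1e-8)
  ref <- glm.fit(cbind(1, X), yy, family = binomial())
  expect_equal(c(ours$beta0, ours$betas), unname(ref$coefficients),
               tolerance = 1e-5)

  expect_error(fit_logistic(c(1, NA), c(0, 1)), "non-finite")
  expect_error(fit_logistic(1:4, c(1, 1, 1, 1)), "both labels")
})

test_that("the unit penalty is negligible for large-scale features (raw-beta penalty)", {
  # on count-scale features the discriminative coefficient is tiny, so a
  # penalty of 1 on the original-scale betas must leave the fit essentially
  # at maximum likelihood
  set.seed(14)
  X <- matrix(rnorm(400, sd = 2000), 200, 2) +
    outer(rep(c(0, 1), each = 100), c(3000, 0))
  y <- rep(c(1, 0), each = 100)
  ours <- fit_logistic(X, y, shrinkage = 1)
  ref <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  expect_equal(predict_logistic(ours, X),
               unname(plogis(drop(cbind(1, X) %*% ref$coefficients))),
               tolerance = 1e-4)
})

test_that("classify_threshold and tune_threshold behave at the boundaries", {
  expect_equal(classify_threshold(c(0.3, 0.7), 0.5), c(0L, 1L))
  expect_equal(classify_threshold(c(0.3, 0.7), 0), c(1L, 1L))
  expect_equal(classify_threshold(c(0.3, 0.7), 1), c(0L, 0L))
  expect_error(classify_threshold(0.5, 1.2), "lambda")
  expect_equal(tune_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
})

test_that("fit_pca matches a dense eigendecomposition oracle up to sign", {
  # collinear cloud: one component carries all variance
  x <- rbind(c(0, 0), c(1, 1), c(2, 2))
  pca <- fit_pca(x, m = 2)
  expect_equal(abs(pca$loadings[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(pca$variances[1] / sum(pca$variances), 1)

  set.seed(8)
  X <- matrix(rnorm(120), 20, 6)
  pca2 <- fit_pca(X, m = 6)
  # oracle: eigendecomposition of the covariance of the centered matrix
  Y <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Y) / (nrow(X) - 1), symmetric = TRUE)
  expect_equal(pca2$variances, eig$values, tolerance = 1e-8)
  for (j in 1:6) {
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(pca2$loadings[, j], v, tolerance = 1e-8)
  }

  # trace conservation: component variances sum to the total variance
  expect_equal(sum(pca2$variances), sum(apply(X, 2, var)))

  # projecting the center gives zero; full reconstruction returns X
  expect_equal(drop(pca_project(matrix(pca2$column_means, 1), pca2)),
               rep(0, 6))
  Z <- pca_project(X, pca2)
  back <- Z %*% t(pca2$loadings) +
    matrix(pca2$column_means, 20, 6, byrow = TRUE)
  expect_equal(back, X, tolerance = 1e-8)

  expect_error(fit_pca(matrix(1, 5, 3)), "degenerate")
  expect_error(pca_project(matrix(0, 2, 4), pca2), "shape error")
})

test_that("pca_summary mirrors the sd / proportion / cumulative layout", {
  set.seed(9)
  pca <- fit_pca(matrix(rnorm(200), 40, 5), m = 5)
  s <- pca_summary(pca)
  expect_equal(s$sd, sqrt(pca$variances[1:5]))
  expect_equal(sum(pca$variances / sum(pca$variances)), 1)
  expect_true(all(diff(s$cumulative) >= 0))
  expect_equal(s$cumulative[5], 1)
})

test_that("roc_auc equals the Mann-Whitney pair count with midrank ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both labels")

  set.seed(10)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    scores <- sample(rnorm(n), n, replace = TRUE)  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
  }
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(12)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(scores^3 + 2 * scores, labels), a)
})

test_that("cross_validate partitions into stratified disjoint folds covering everything", {
  cfg <- small_effect_config(n_per_class = 100, delta = 1.4, noise_sd = 5)
  ds <- generate_dataset(cfg)
  cv <- cross_validate(ds, method_lra(), k = 10, seed = 2)
  expect_length(cv$fold_aucs, 10)
  expect_equal(cv$mean_auc, mean(cv$fold_aucs))
  expect_equal(cv$sem, sd(cv$fold_aucs) / sqrt(10))
  all_idx <- sort(unlist(cv$folds))
  expect_identical(all_idx, seq_along(ds$labels))
  expect_equal(lengths(cv$folds), rep(20, 10))
  for (f in cv$folds)
    expect_setequal(unique(ds$labels[f]), c(0, 1))
  expect_error(cross_validate(ds, method_lra(), k = 1000), "more folds")
})

test_that("permutation importance isolates the informative feature", {
  # a coefficient of exactly zero yields a zero score
  set.seed(13)
  feats <- cbind(rnorm(200), rnorm(200))
  labs <- as.integer(feats[, 1] + rnorm(200, sd = 0.3) > 0)
  model <- list(beta0 = 0, betas = c(3, 0))
  imp <- permutation_importance(function(f) predict_logistic(model, f),
                                feats, labs, n_perm = 5, seed = 1)
  expect_equal(imp$scores[2], 0)
  expect_gt(imp$scores[1], 0.2)

  # determinism under a fixed seed, even with a single permutation
  imp2 <- permutation_importance(function(f) predict_logistic(model, f),
                                 feats, labs, n_perm = 1, seed = 99)
  imp3 <- permutation_importance(function(f) predict_logistic(model, f),
                                 feats, labs, n_perm = 1, seed = 99)
  expect_identical(imp2$scores, imp3$scores)
  expect_error(permutation_importance(identity, feats, labs, n_perm = 0),
               "n_perm")
})
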