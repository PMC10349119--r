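#' Class-mean spectra
#'
#' Columnwise mean spectrum of each class of a training set: `h1` over the
#' label-1 rows, `h2` over the label-0 rows.
#'
#' @param train A [spectral_dataset()] containing both labels.
#' @return List with numeric vectors `h1` and `h2`.
#' @export
class_means <- function(train) {
  stopifnot(inherits(train, "spectral_dataset"))
  i1 <- train$labels == 1L
  if (!any(i1) || all(i1))
    stop("insufficient data: both labels must be present")
  list(h1 = colMeans(train$intensities[i1, , drop = FALSE]),
       h2 = colMeans(train$intensities[!i1, , drop = FALSE]))
}

#' Squared l2 distance between a spectrum and a reference
#'
#' `sum((x - h)^2)`, with no square root: the quantity the tau-weighted
#' nearest-mean rule thresholds.
#'
#' @param x,h Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
l2_distance_sq <- function(x, h) {
  if (length(x) != length(h))
    stop("shape error: vectors of length ", length(x), " and ", length(h))
  sum((x - h)^2)
}

# Squared distances of every row of x to h, without forming copies per row.
row_dist_sq <- function(x, h) {
  sweep_sq <- x - matrix(h, nrow(x), length(h), byrow = TRUE)
  rowSums(sweep_sq^2)
}

#' tau-weighted nearest-mean classifier
#'
#' Assigns class 1 iff `tau * d1 <= (1 - tau) * d2`, where `d1`, `d2` are the
#' squared l2 distances to the class-1 and class-0 mean spectra. `tau = 0.5`
#' is the plain nearest-centroid rule; `tau` trades off the two error types.
#'
#' @param x A spectrum (vector) or an `N x p` matrix of spectra.
#' @param model List with `means` (from [class_means()]) and `tau` in [0, 1].
#' @return Integer class labels (0/1), one per spectrum.
#' @export
l2d_classify <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d1 <- row_dist_sq(x, model$means$h1)
  d2 <- row_dist_sq(x, model$means$h2)
  as.integer(model$tau * d1 <= (1 - model$tau) * d2)
}

#' Margin score of the tau-weighted nearest-mean rule
#'
#' `(1 - tau) * d2 - tau * d1`; positive margins are classified 1. Used as
#' the continuous score when computing ROC curves for this classifier.
#'
#' @inheritParams l2d_classify
#' @return Numeric score vector.
#' @export
l2d_margin <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d1 <- row_dist_sq(x, model$means$h1)
  d2 <- row_dist_sq(x, model$means$h2)
  (1 - model$tau) * d2 - model$tau * d1
}

#' Fit the tau-weighted nearest-mean classifier
#'
#' Computes the class-mean spectra and selects `tau` over a grid by ten-fold
#' cross-validated ROC-AUC of the margin score, ties broken toward 0.5.
#'
#' @param train A [spectral_dataset()].
#' @param tau_grid Candidate `tau` values in [0, 1]; default 51 equispaced.
#' @param k Folds for the internal tuning CV.
#' @param seed Seed for the tuning partition.
#' @return List with `means`, `tau`, and `tau_cv` (per-tau mean CV AUC).
#' @export
fit_l2d <- function(train, tau_grid = seq(0, 1, length.out = 51),
                    k = 10, seed = 1L) {
  stopifnot(inherits(train, "spectral_dataset"))
  if (length(tau_grid) == 0) stop("invalid config: empty tau grid")
  if (any(tau_grid < 0 | tau_grid > 1))
    stop("invalid config: tau grid must lie in [0, 1]")
  folds <- stratified_folds(train$labels, k, seed)
  cv_auc <- matrix(NA_real_, length(folds), length(tau_grid))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    m <- class_means(subset_rows(train, -test_idx))
    xt <- train$intensities[test_idx, , drop = FALSE]
    yt <- train$labels[test_idx]
    d1 <- row_dist_sq(xt, m$h1)
    d2 <- row_dist_sq(xt, m$h2)
    for (j in seq_along(tau_grid)) {
      tau <- tau_grid[j]
      cv_auc[f, j] <- roc_auc((1 - tau) * d2 - tau * d1, yt)
    }
  }
  mean_auc <- colMeans(cv_auc)
  best <- which(mean_auc == max(mean_auc))
  tau <- tau_grid[best[which.min(abs(tau_grid[best] - 0.5))]]
  list(means = class_means(train), tau = tau,
       tau_cv = stats::setNames(mean_auc, tau_grid))
}

#' Global-mean feature
#'
#' The arithmetic mean intensity over the (already region-restricted)
#' spectrum: the single predictor of the simplest logistic model.
#'
#' @param x A spectrum (vector) or matrix of spectra.
#' @return Scalar, or one mean per row.
#' @export
global_mean_feature <- function(x) {
  if (is.null(dim(x))) mean(x) else rowMeans(x)
}

#' Average-pooling scheme over wavenumber sub-domains
#'
#' Consecutive boundaries define non-overlapping, generally non-equispaced
#' bins covering the region; the first bin is closed on both ends, later bins
#' are left-open `(lo, hi]`. Each bin contributes one feature: the mean
#' intensity of the axis points it contains.
#'
#' @param boundaries Strictly increasing numeric cut points (length
#'   `n_features + 1`).
#' @return Object of class `pooling_scheme`.
#' @export
pooling_scheme <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0))
    stop("invalid scheme: boundaries must be strictly increasing, length >= 2")
  structure(list(boundaries = boundaries,
                 n_features = length(boundaries) - 1L),
            class = "pooling_scheme")
}

#' @rdname pooling_scheme
#' @details `pooling_lw()` (4 features) and `pooling_hw()` (3 features) are
#'   the defaults for the low- and high-wavenumber regions; their cells
#'   isolate the Si-band sub-domain 480-549 cm^-1 and the CH sub-domains
#'   2701-3200 and 3200-3400 cm^-1.
#' @export
pooling_lw <- function() pooling_scheme(c(125.25, 234, 360, 480, 549.27))

#' @rdname pooling_scheme
#' @export
pooling_hw <- function() pooling_scheme(c(2303.16, 2700.5, 3200, 3399.83))

#' Average pooling of spectra
#'
#' @param x A spectrum (vector) or `N x p` matrix.
#' @param scheme A [pooling_scheme()].
#' @param axis Wavenumber axis matching the columns of `x`.
#' @return Feature vector (or `N x n_features` matrix), bins ordered by
#'   wavenumber.
#' @export
average_pooling <- function(x, scheme, axis) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(axis))
    stop("shape error: axis length does not match spectrum length")
  b <- scheme$boundaries
  bin <- findInterval(axis, b, left.open = TRUE)
  bin[axis == b[1]] <- 1L  # first bin closed on the left
  feats <- matrix(NA_real_, nrow(x), scheme$n_features)
  for (j in seq_len(scheme$n_features)) {
    cols <- which(bin == j & axis <= b[length(b)])
    if (length(cols) == 0)
      stop("invalid scheme: sub-domain (", b[j], ", ", b[j + 1],
           "] contains no axis points")
    feats[, j] <- rowMeans(x[, cols, drop = FALSE])
  }
  if (nrow(feats) == 1) drop(feats) else feats
}

#' Ridge-penalized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood minus
#' `shrinkage/2 * sum(beta^2)` (intercept unpenalized) by Newton iterations.
#' With a handful of pooled or principal-component features this is exact and
#' deterministic; the penalty keeps coefficients finite even under perfect
#' separation.
#'
#' @param features `N x m` numeric matrix (or vector for m = 1).
#' @param labels Binary 0/1 vector of length N.
#' @param shrinkage L2 penalty weight (default 1).
#' @param max_iter,tol Newton controls.
#' @return List with `beta0`, `betas`, `shrinkage`, `converged`.
#' @export
fit_logistic <- function(features, labels, shrinkage = 1,
                         max_iter = 100, tol = 1e-10) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (any(!is.finite(features))) stop("data error: non-finite feature values")
  labels <- as.numeric(labels)
  if (all(labels == 1) || all(labels == 0))
    stop("insufficient data: both labels must be present")
  n <- nrow(features)
  m <- ncol(features)
  # center/scale internally for Newton conditioning; coefficients mapped back
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  X <- cbind(1, z)
  # the penalty applies to the original-scale betas: beta_orig = beta_std/scl,
  # so in standardized coordinates the weight per coefficient is s/scl^2
  pen <- c(0, shrinkage / scl^2)
  beta <- rep(0, m + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, labels - mu)) - pen * beta
    hess <- crossprod(X * w, X) + diag(pen, m + 1)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  betas <- beta[-1] / scl
  list(beta0 = beta[1] - sum(betas * ctr), betas = betas,
       shrinkage = shrinkage, converged = converged)
}

#' Predicted class-1 probabilities of a logistic model
#'
#' @param model A fit from [fit_logistic()].
#' @param features Matrix (or vector) of predictors.
#' @return Probabilities in (0, 1).
#' @export
predict_logistic <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  stats::plogis(model$beta0 + drop(features %*% model$betas))
}

#' Threshold probabilities into class labels
#'
#' @param probs Probabilities in [0, 1].
#' @param lambda Decision cut in [0, 1]; class 1 iff `prob >= lambda`.
#' @return Integer 0/1 vector.
#' @export
classify_threshold <- function(probs, lambda) {
  if (lambda < 0 || lambda > 1)
    stop("invalid config: lambda must lie in [0, 1]")
  as.integer(probs >= lambda)
}

#' Tune the probability threshold by cross-validated accuracy
#'
#' ROC-AUC does not depend on the cut, so the threshold is tuned on
#' classification accuracy over a grid, ties broken toward 0.5.
#'
#' @param probs Out-of-fold predicted probabilities.
#' @param labels Matching true labels.
#' @param grid Candidate cuts; default 51 equispaced points on [0, 1].
#' @return The selected cut.
#' @export
tune_threshold <- function(probs, labels, grid = seq(0, 1, length.out = 51)) {
  acc <- vapply(grid, function(l) mean(classify_threshold(probs, l) == labels),
                numeric(1))
  best <- which(acc == max(acc))
  grid[best[which.min(abs(grid[best] - 0.5))]]
}

#' Principal components analysis of a spectral training set
#'
#' Columns are centered with the training means; principal directions are the
#' eigenvectors of the empirical covariance of the centered matrix, ordered by
#' decreasing variance (computed via SVD). Loadings have a fixed sign: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x An `N x p` matrix or a [spectral_dataset()].
#' @param m Retained components: a fixed integer, or `NULL` to keep the
#'   smallest m whose cumulative proportion of variance reaches `cum_threshold`
#'   (capped at `max_m`).
#' @param cum_threshold,max_m Policy controls for automatic `m`.
#' @return List with `loadings` (`p x m`), `variances` (all p component
#'   variances), `m`, `column_means`.
#' @export
fit_pca <- function(x, m = NULL, cum_threshold = 0.999, max_m = 5) {
  if (inherits(x, "spectral_dataset")) x <- x$intensities
  if (nrow(x) < 2) stop("insufficient data: need at least 2 spectra")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  variances <- pc$sdev^2
  if (all(variances < 1e-12)) stop("degenerate input: zero-variance data")
  prop <- variances / sum(variances)
  if (is.null(m)) {
    m <- min(which(cumsum(prop) >= cum_threshold), max_m)
    m <- min(m, max_m)
  }
  m <- min(m, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m))
    if (loadings[which.max(abs(loadings[, j])), j] < 0)
      loadings[, j] <- -loadings[, j]
  dimnames(loadings) <- NULL
  list(loadings = loadings, variances = variances, m = m,
       column_means = unname(pc$center))
}

#' Project spectra onto fitted principal components
#'
#' @param x Matrix or [spectral_dataset()] on the same axis as the fit.
#' @param model A fit from [fit_pca()].
#' @return `N x m` matrix of component scores.
#' @export
pca_project <- function(x, model) {
  if (inherits(x, "spectral_dataset")) x <- x$intensities
  if (ncol(x) != length(model$column_means))
    stop("shape error: data has ", ncol(x), " columns, model expects ",
         length(model$column_means))
  sweep(x, 2, model$column_means) %*% model$loadings
}

#' Variance table of a PCA fit
#'
#' Standard deviation, proportion of variance and cumulative proportion for
#' the first `m` components.
#'
#' @param model A fit from [fit_pca()].
#' @param m Number of components to tabulate (default the fit's `m`).
#' @return A data.frame with one row per component.
#' @export
pca_summary <- function(model, m = model$m) {
  prop <- model$variances / sum(model$variances)
  data.frame(component = seq_len(m),
             sd = sqrt(model$variances[seq_len(m)]),
             proportion = prop[seq_len(m)],
             cumulative = cumsum(prop)[seq_len(m)])
}

#' ROC-AUC by the Mann-Whitney identity
#'
#' Probability that a uniformly random positive instance receives a higher
#' score than a uniformly random negative one, ties counted one half.
#'
#' @param scores Numeric scores, larger meaning more class-1.
#' @param labels Binary 0/1 labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: both labels must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold partition: shuffles each label group under the seed and
# deals its members round-robin, so every fold holds both labels.
stratified_folds <- function(labels, k, seed) {
  if (k > length(labels)) stop("invalid config: more folds than observations")
  set.seed(seed)
  folds <- vector("list", k)
  for (lab in unique(labels)) {
    idx <- sample(which(labels == lab))
    grp <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

#' Ten-fold cross-validated ROC-AUC of a classification method
#'
#' Randomly partitions the dataset into `k` label-stratified folds; each fold
#' is scored once by a model fitted on the other `k - 1`. Reports per-fold
#' AUCs, their mean, and the standard error of the mean over folds.
#'
#' @param ds A [spectral_dataset()].
#' @param method A method object (see [method_lra()] and friends): a list with
#'   `fit(train_ds)` returning a fitted object and `score(fitted, test_ds)`
#'   returning continuous scores.
#' @param k Number of folds (default 10).
#' @param seed Seed for the partition (and for any stochastic fitting).
#' @return List with `fold_aucs`, `mean_auc`, `sem`, `folds`.
#' @export
cross_validate <- function(ds, method, k = 10, seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  folds <- stratified_folds(ds$labels, k, seed)
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- subset_rows(ds, -test_idx)
    test <- subset_rows(ds, test_idx)
    fitted <- method$fit(train, seed = seed + f)
    fold_aucs[f] <- roc_auc(method$score(fitted, test), test$labels)
  }
  list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
       sem = stats::sd(fold_aucs) / sqrt(k), folds = folds)
}

#' Permutation importance of feature columns
#'
#' For each feature column: the model's test ROC-AUC minus the mean test
#' ROC-AUC after independently shuffling that column (other columns
#' untouched), averaged over `n_perm` shuffles. Large positive scores mark
#' features the model's discrimination relies on.
#'
#' @param score_fun Function mapping a feature matrix to continuous scores
#'   (e.g. a fitted model's probability predictor).
#' @param features `N x m` test feature matrix.
#' @param labels Test labels (both classes present).
#' @param n_perm Shuffles per column (default 30).
#' @param seed RNG seed.
#' @return List with `scores` (AUC drop per feature), `sd` (dispersion of the
#'   shuffled AUCs per feature), `base_auc`, `n_perm`.
#' @export
permutation_importance <- function(score_fun, features, labels,
                                   n_perm = 30, seed = 1L) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (n_perm < 1) stop("invalid config: n_perm must be >= 1")
  set.seed(seed)
  base_auc <- roc_auc(score_fun(features), labels)
  m <- ncol(features)
  scores <- numeric(m)
  disp <- numeric(m)
  n <- nrow(features)
  for (j in seq_len(m)) {
    aucs <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      shuffled <- features
      shuffled[, j] <- features[sample.int(n), j]
      aucs[r] <- roc_auc(score_fun(shuffled), labels)
    }
    scores[j] <- base_auc - mean(aucs)
    disp[j] <- stats::sd(aucs)
  }
  list(scores = scores, sd = disp, base_auc = base_auc, n_perm = n_perm)
}

#' Classification method objects
#'
#' Each constructor returns a list with `name`, `fit(train, seed)` and
#' `score(fitted, test)` suitable for [cross_validate()]:
#' \describe{
#'   \item{`method_lra()`}{ridge logistic regression on the global mean
#'     intensity (the simplest, fully global model).}
#'   \item{`method_l2d()`}{the tau-weighted nearest-mean rule, scored by its
#'     margin.}
#'   \item{`method_lrp(scheme)`}{ridge logistic regression on average-pooled
#'     sub-band means.}
#'   \item{`method_pca()`}{ridge logistic regression on the leading principal
#'     component scores.}
#' }
#'
#' @param shrinkage L2 penalty weight for the logistic fits (default 1).
#' @param tau_grid Grid for the nearest-mean weight tau.
#' @param scheme A [pooling_scheme()]; defaults to [pooling_lw()]/
#'   [pooling_hw()] picked by region in [run_comparison()].
#' @param m,cum_threshold,max_m Component policy for [fit_pca()].
#' @return A method object (list).
#' @name methods
NULL

#' @rdname methods
#' @export
method_lra <- function(shrinkage = 1) {
  list(name = "LRA",
       fit = function(train, seed = 1L) {
         fit_logistic(global_mean_feature(train$intensities), train$labels,
                      shrinkage = shrinkage)
       },
       score = function(fitted, test) {
         predict_logistic(fitted, global_mean_feature(test$intensities))
       })
}

#' @rdname methods
#' @export
method_l2d <- function(tau_grid = seq(0, 1, length.out = 51)) {
  list(name = "L2D",
       fit = function(train, seed = 1L) {
         fit_l2d(train, tau_grid = tau_grid, seed = seed)
       },
       score = function(fitted, test) l2d_margin(test$intensities, fitted))
}

#' @rdname methods
#' @export
method_lrp <- function(scheme, shrinkage = 1) {
  force(scheme)
  list(name = "LRP",
       fit = function(train, seed = 1L) {
         feats <- average_pooling(train$intensities, scheme, train$wavenumbers)
         list(model = fit_logistic(feats, train$labels, shrinkage = shrinkage),
              scheme = scheme)
       },
       score = function(fitted, test) {
         feats <- average_pooling(test$intensities, fitted$scheme,
                                  test$wavenumbers)
         predict_logistic(fitted$model, feats)
       })
}

#' @rdname methods
#' @export
method_pca <- function(m = NULL, cum_threshold = 0.999, max_m = 5,
                       shrinkage = 1) {
  list(name = "PCA",
       fit = function(train, seed = 1L) {
         pca <- fit_pca(train$intensities, m = m,
                        cum_threshold = cum_threshold, max_m = max_m)
         z <- pca_project(train$intensities, pca)
         list(pca = pca,
              model = fit_logistic(z, train$labels, shrinkage = shrinkage))
       },
       score = function(fitted, test) {
         predict_logistic(fitted$model,
                          pca_project(test$intensities, fitted$pca))
       })
}
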