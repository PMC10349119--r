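#' Standardize a spectrum
#'
#' Removes the mean and makes the standard deviation exactly one, using the
#' population SD (divide by p), so the output satisfies mean 0 / SD 1 as an
#' identity.
#'
#' @param x Numeric vector with positive dispersion.
#' @return Standardized vector.
#' @export
standardize_spectrum <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("zero-variance error: constant spectrum cannot be standardized")
  (x - mu) / s
}

#' Pairwise cosine affinity matrix
#'
#' `kappa(x, y) = <x, y> / sqrt(<x, x> <y, y>)` for every pair of rows:
#' symmetric, unit diagonal, entries in [-1, 1]. On standardized spectra this
#' equals the Pearson correlation of the raw spectra.
#'
#' @param X `N x p` matrix with no zero-norm rows.
#' @return `N x N` affinity matrix.
#' @export
cosine_affinity <- function(X) {
  if (inherits(X, "spectral_dataset")) X <- X$intensities
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("degenerate input: zero-norm row ", which(nrm == 0)[1])
  kappa <- tcrossprod(X / nrm)
  kappa[kappa > 1] <- 1
  kappa[kappa < -1] <- -1
  diag(kappa) <- 1
  kappa
}

#' Two-way spectral clustering of an affinity matrix
#'
#' Negative affinities are clipped to zero (normalized graph cuts assume
#' non-negative weights), the symmetric normalized Laplacian
#' `I - D^{-1/2} K D^{-1/2}` is formed, the data are embedded in the k
#' eigenvectors of smallest eigenvalue, and k-means (10 seeded restarts)
#' partitions the embedding.
#'
#' @param kappa `N x N` symmetric affinity matrix.
#' @param k Number of clusters (2).
#' @param seed Seed for the k-means restarts.
#' @return Integer cluster labels in `{0, 1}`.
#' @export
spectral_clustering <- function(kappa, k = 2, seed = 1L) {
  stopifnot(is.matrix(kappa), nrow(kappa) == ncol(kappa))
  if (nrow(kappa) < k) stop("insufficient data: fewer instances than clusters")
  W <- pmax(kappa, 0)
  d <- rowSums(W)
  if (any(d == 0))
    stop("degenerate input: isolated vertex with zero affinity")
  dinv <- 1 / sqrt(d)
  L <- diag(nrow(W)) - (dinv * W) * rep(dinv, each = nrow(W))
  L <- (L + t(L)) / 2
  ev <- eigen(L, symmetric = TRUE)
  n_zero <- sum(ev$values < 1e-10)
  if (n_zero > k)
    warning("ambiguity: graph has ", n_zero, " connected components (> k); ",
            "partition may be arbitrary among them")
  emb <- ev$vectors[, ncol(ev$vectors) - seq_len(k) + 1, drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = 10)
  as.integer(km$cluster - 1L)
}

#' Matthews correlation coefficient from confusion-matrix counts
#'
#' `(n00 n11 - n01 n10) / sqrt((n00+n10)(n00+n01)(n11+n10)(n11+n01))`, where
#' `n_ij` counts instances with true label i and predicted label j. If any
#' marginal factor is zero (e.g. everything predicted into one cluster) the
#' coefficient is defined as 0.
#'
#' @param n00,n01,n10,n11 Non-negative counts.
#' @return Value in [-1, 1].
#' @export
mcc <- function(n00, n01, n10, n11) {
  stopifnot(n00 >= 0, n01 >= 0, n10 >= 0, n11 >= 0)
  # double arithmetic: the marginal product overflows integers for N ~ 200+
  n00 <- as.numeric(n00); n01 <- as.numeric(n01)
  n10 <- as.numeric(n10); n11 <- as.numeric(n11)
  denom <- (n00 + n10) * (n00 + n01) * (n11 + n10) * (n11 + n01)
  if (denom == 0) return(0)
  (n00 * n11 - n01 * n10) / sqrt(denom)
}

confusion_counts <- function(true, pred) {
  c(n00 = sum(true == 0 & pred == 0), n01 = sum(true == 0 & pred == 1),
    n10 = sum(true == 1 & pred == 0), n11 = sum(true == 1 & pred == 1))
}

#' Score a clustering against true labels
#'
#' Cluster indices carry no class meaning, so both labelings of the two
#' clusters are evaluated and the orientation with the larger Matthews
#' correlation is reported, together with the density-form confusion matrix
#' (each cell divided by N).
#'
#' @param pred Predicted cluster labels in `{0, 1}`.
#' @param true True labels in `{0, 1}`, same length.
#' @return List with `mcc`, `counts` (named n00, n01, n10, n11), `densities`,
#'   and `flipped` (whether the relabeled orientation won).
#' @export
evaluate_clustering <- function(pred, true) {
  if (length(pred) != length(true))
    stop("shape error: ", length(pred), " predictions vs ", length(true),
         " labels")
  a <- confusion_counts(true, pred)
  b <- confusion_counts(true, 1L - pred)
  mcc_a <- mcc(a["n00"], a["n01"], a["n10"], a["n11"])
  mcc_b <- mcc(b["n00"], b["n01"], b["n10"], b["n11"])
  if (mcc_b > mcc_a) {
    counts <- b; best <- mcc_b; flipped <- TRUE
  } else {
    counts <- a; best <- mcc_a; flipped <- FALSE
  }
  list(mcc = unname(best), counts = counts,
       densities = counts / length(true), flipped = flipped)
}

#' Unsupervised differentiation of two samples
#'
#' The full clustering route: per-spectrum standardization, cosine affinity,
#' two-way spectral clustering, and MCC scoring against the true labels.
#'
#' @param ds A [spectral_dataset()].
#' @param seed Seed for the clustering.
#' @return As [evaluate_clustering()], plus `pred` (cluster labels).
#' @export
cluster_comparison <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  Xs <- t(apply(ds$intensities, 1, standardize_spectrum))
  kappa <- cosine_affinity(Xs)
  pred <- spectral_clustering(kappa, k = 2, seed = seed)
  out <- evaluate_clustering(pred, ds$labels)
  out$pred <- pred
  out
}
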