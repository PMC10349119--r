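#' Polynomial background (fluorescence) correction
#'
#' Estimates a low-order polynomial baseline and subtracts it. The default
#' estimator is iteratively reweighted: after each fit, points lying above the
#' current baseline (peaks) are clipped down to it before refitting, so the
#' polynomial tracks the fluorescence background rather than the Raman bands
#' (the classic modified-polyfit scheme). `iterative = FALSE` gives a single
#' ordinary least-squares fit.
#'
#' @param x Intensity vector.
#' @param order Polynomial degree (default 3).
#' @param iterative Clip-and-refit until convergence (default `TRUE`).
#' @param max_iter,tol Convergence controls for the iterative scheme.
#' @return `x` minus the estimated baseline; same length as `x`.
#' @export
background_correct <- function(x, order = 3, iterative = TRUE,
                               max_iter = 100, tol = 1e-8) {
  n <- length(x)
  if (order < 0) stop("invalid config: order must be >= 0")
  if (order >= n) stop("invalid config: order (", order,
                       ") must be below the number of points (", n, ")")
  basis <- cbind(1, stats::poly(seq_len(n), degree = max(order, 1)))
  if (order == 0) basis <- basis[, 1, drop = FALSE]
  fit_poly <- function(y) basis %*% qr.coef(qr(basis), y)
  y <- x
  baseline <- fit_poly(y)
  if (iterative) {
    scale <- max(diff(range(x)), 1e-12)
    for (i in seq_len(max_iter)) {
      y_new <- pmin(y, baseline)
      baseline_new <- fit_poly(y_new)
      if (max(abs(baseline_new - baseline)) < tol * scale) {
        baseline <- baseline_new
        break
      }
      y <- y_new
      baseline <- baseline_new
    }
  }
  as.numeric(x - baseline)
}

#' Decision-surface outlier rejection
#'
#' For each label group separately (the default, matching per-sample average
#' spectra; `pooled = TRUE` uses the whole set), computes the pointwise mean
#' and standard deviation, and discards every spectrum with at least one point
#' strictly outside the band mean +/- k * SD. Points exactly on the surface
#' count as inside.
#'
#' @param ds A [spectral_dataset()].
#' @param k Band half-width in SD units (default 3).
#' @param pooled Use a single mean/SD envelope over all spectra.
#' @return List with `dataset` (survivors) and `removed` (row indices of the
#'   input that were discarded).
#' @export
remove_outliers <- function(ds, k = 3, pooled = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (k <= 0) stop("invalid config: k must be > 0")
  groups <- if (pooled) list(seq_along(ds$labels)) else
    list(which(ds$labels == 1L), which(ds$labels == 0L))
  removed <- integer(0)
  for (idx in groups) {
    if (length(idx) == 0) next
    if (length(idx) < 2)
      stop("insufficient data: a label group has fewer than 2 spectra")
    xg <- ds$intensities[idx, , drop = FALSE]
    mu <- colMeans(xg)
    sdv <- apply(xg, 2, stats::sd)
    lo <- mu - k * sdv
    hi <- mu + k * sdv
    out <- vapply(seq_along(idx), function(i)
      any(xg[i, ] < lo | xg[i, ] > hi), logical(1))
    removed <- c(removed, idx[out])
  }
  removed <- sort(removed)
  keep <- setdiff(seq_along(ds$labels), removed)
  list(dataset = subset_rows(ds, keep), removed = removed)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by its Savitzky-Golay filtered version: local
#' least-squares polynomial fits expressed as convolution coefficients, with
#' the end points handled by polynomial fits on the truncated windows. An
#' even `window` is rejected with a pointer to the nearest odd value (a
#' symmetric window must be odd).
#'
#' @param ds A [spectral_dataset()] or a single numeric spectrum.
#' @param window Window length in points; odd, `> polyorder`, `<= p`
#'   (default 91).
#' @param polyorder Fitting polynomial degree (default 3).
#' @return Smoothed object of the same type as the input.
#' @export
sg_smooth <- function(ds, window = 91, polyorder = 3) {
  if (window %% 2 == 0)
    stop("invalid config: Savitzky-Golay window must be odd; use ",
         window + 1, " or ", window - 1)
  if (window <= polyorder)
    stop("invalid config: window must exceed polyorder")
  p <- if (inherits(ds, "spectral_dataset")) length(ds$wavenumbers) else length(ds)
  if (window > p)
    stop("invalid config: window (", window, ") exceeds spectrum length (", p, ")")
  if (!inherits(ds, "spectral_dataset"))
    return(as.numeric(signal::sgolayfilt(ds, p = polyorder, n = window)))
  sm <- t(apply(ds$intensities, 1, signal::sgolayfilt,
                p = polyorder, n = window))
  spectral_dataset(ds$wavenumbers, sm, ds$labels, ds$sample_names)
}

#' Full preprocessing pipeline
#'
#' Stage order: polynomial background correction (optional; skip for data
#' already background-corrected by the instrument), mean +/- k SD outlier
#' rejection, Savitzky-Golay smoothing.
#'
#' @param ds A [spectral_dataset()].
#' @param background_order Baseline polynomial degree; `NA` skips the stage.
#' @param sd_multiplier Outlier band half-width in SD units.
#' @param sg_window,sg_polyorder Savitzky-Golay controls.
#' @return List with `dataset`, `removed` (outlier row indices), and `stages`
#'   (the stage order actually executed).
#' @export
preprocess <- function(ds, background_order = 3, sd_multiplier = 3,
                       sg_window = 91, sg_polyorder = 3) {
  stopifnot(inherits(ds, "spectral_dataset"))
  stages <- character(0)
  if (!is.na(background_order)) {
    ds <- spectral_dataset(ds$wavenumbers,
                           t(apply(ds$intensities, 1, background_correct,
                                   order = background_order)),
                           ds$labels, ds$sample_names)
    stages <- c(stages, "background")
  }
  filt <- remove_outliers(ds, k = sd_multiplier)
  stages <- c(stages, "outliers")
  ds <- sg_smooth(filt$dataset, window = sg_window, polyorder = sg_polyorder)
  stages <- c(stages, "smooth")
  list(dataset = ds, removed = filt$removed, stages = stages)
}
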