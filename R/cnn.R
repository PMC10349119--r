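# 1-D purely convolutional network for spectral classification.
#
# Fixed architecture: 3 x [conv(64 filters, kernel 3, valid, softplus) ->
# max-pool(2) -> dropout(0.25)], flatten, dense(16, softplus),
# dense(1, sigmoid). Trained with mini-batch ADAM on binary cross-entropy.
# The forward/backward kernels live in src/cnn.cpp; this file holds the
# model container, the ADAM training loop, and the saliency post-processing.

CNN_KERNEL <- 3L
CNN_FILTERS <- 64L
CNN_POOL <- 2L
CNN_DROPOUT <- 0.25
CNN_DENSE <- 16L

#' Layer-by-layer output lengths of the convolutional stack
#'
#' Each block maps length L to L - 2 (valid convolution, kernel 3) then
#' floor(L / 2) (max-pool 2). Returns the lengths after every conv and pool
#' stage, in order.
#'
#' @param input_length Number of spectral points fed to the network.
#' @return Integer vector of 6 lengths: conv1, pool1, conv2, pool2, conv3,
#'   pool3.
#' @export
cnn_out_lengths <- function(input_length) {
  l <- as.integer(input_length)
  out <- integer(6)
  for (b in 1:3) {
    l <- l - (CNN_KERNEL - 1L)
    out[2L * b - 1L] <- l
    l <- l %/% CNN_POOL
    out[2L * b] <- l
  }
  out
}

#' Trainable parameter count of the network
#'
#' Sum of conv weight/bias, dense weight/bias counts for a given input
#' length; 50593 for the 221-point low-wavenumber window.
#'
#' @inheritParams cnn_out_lengths
#' @return Integer parameter count.
#' @export
cnn_param_count <- function(input_length) {
  lens <- cnn_out_lengths(input_length)
  flat <- lens[6] * CNN_FILTERS
  (1L * CNN_KERNEL * CNN_FILTERS + CNN_FILTERS) +
    2L * (CNN_FILTERS * CNN_KERNEL * CNN_FILTERS + CNN_FILTERS) +
    (flat * CNN_DENSE + CNN_DENSE) +
    (CNN_DENSE * 1L + 1L)
}

#' Build the untrained network
#'
#' Initializes weights (He-scaled normal draws, zero biases) for the fixed
#' architecture. The input must be long enough to survive three valid
#' convolution + pooling stages with a non-empty feature map. Besides the
#' trainable weights the model carries five fixed per-layer scale constants
#' (all 1 at build time), calibrated from the training data when training
#' starts; see [train_cnn()].
#'
#' @param input_length Number of spectral points.
#' @param seed Seed controlling the weight draw.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(input_length, seed = 1L) {
  lens <- cnn_out_lengths(input_length)
  if (any(lens < 1))
    stop("invalid config: input length ", input_length,
         " too short for three conv+pool stages (need >= 30)")
  set.seed(seed)
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nin)), nr, nc)
  flat <- lens[6] * CNN_FILTERS
  params <- list(
    W1 = he(1 * CNN_KERNEL, 1 * CNN_KERNEL, CNN_FILTERS), b1 = rep(0, CNN_FILTERS),
    W2 = he(CNN_FILTERS * CNN_KERNEL, CNN_FILTERS * CNN_KERNEL, CNN_FILTERS),
    b2 = rep(0, CNN_FILTERS),
    W3 = he(CNN_FILTERS * CNN_KERNEL, CNN_FILTERS * CNN_KERNEL, CNN_FILTERS),
    b3 = rep(0, CNN_FILTERS),
    W4 = he(flat, flat, CNN_DENSE), b4 = rep(0, CNN_DENSE),
    W5 = he(CNN_DENSE, CNN_DENSE, 1), b5 = 0
  )
  structure(list(params = params, scales = rep(1, 5),
                 input_length = as.integer(input_length),
                 lengths = lens, trained = FALSE, loss_trace = numeric(0)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %d, 3x[conv64x3/softplus -> pool2 -> drop .25], dense16, dense1/sigmoid\n",
              x$input_length))
  cat(sprintf("  %d parameters, %strained\n", cnn_param_count(x$input_length),
              if (x$trained) "" else "un"))
  invisible(x)
}

#' Train the network
#'
#' Mini-batch ADAM on binary cross-entropy, raw intensities in (the spectra
#' are neither rescaled nor otherwise transformed). With
#' `validation_split > 0`, a label-stratified subset is held out and training
#' stops once the validation loss has not improved for `patience` epochs,
#' restoring the best weights. Fully deterministic given the model's build
#' seed and `seed`.
#'
#' Before the first step, the model's fixed per-layer scale constants are
#' calibrated on a probe batch with dropout active: each constant is set so
#' the layer's pre-activations have unit SD, and the biases are shifted to
#' center them. Raw intensities can sit orders of magnitude away from the
#' unit scale the usual random initialization assumes; without this
#' reparameterization of the initial weights the softplus units saturate
#' into a constant-output network that gradient descent cannot leave. The
#' constants are part of the initialization, not trained, and no
#' transformation is applied to the data itself.
#'
#' @param model An untrained (or trained) [build_cnn()] model.
#' @param X `N x p` intensity matrix, `p` equal to the model's input length.
#' @param y Binary 0/1 labels.
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param lr ADAM learning rate (default 0.001).
#' @param validation_split Fraction held out for early stopping (default 0.1;
#'   0 disables early stopping).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Seed for shuffling, dropout and the validation split.
#' @param normalize_init Calibrate the fixed scale constants before training
#'   (default `TRUE`).
#' @return The trained `cnn_model`, with `loss_trace` (per-epoch mean
#'   training BCE) and `epochs_run` filled in.
#' @export
train_cnn <- function(model, X, y, epochs = 50, batch_size = 64, lr = 0.001,
                      validation_split = 0.1, patience = 10, seed = 1L,
                      normalize_init = TRUE) {
  stopifnot(inherits(model, "cnn_model"))
  if (ncol(X) != model$input_length)
    stop("shape error: data has ", ncol(X), " columns, model expects ",
         model$input_length)
  y <- as.numeric(y)
  if (all(y == 1) || all(y == 0))
    stop("insufficient data: both labels must be present")
  set.seed(seed)
  n <- nrow(X)
  if (validation_split > 0) {
    n_val <- max(2L, floor(validation_split * n))
    val_idx <- c(sample(which(y == 1), max(1L, round(n_val * mean(y == 1)))),
                 sample(which(y == 0), max(1L, round(n_val * mean(y == 0)))))
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  params <- model$params
  scales <- model$scales
  if (normalize_init && !model$trained) {
    # probe must mix both classes, or the deepest scale amplifies the
    # between-class shift and saturates the output at initialization
    probe <- Xtr[sample.int(nrow(Xtr), min(128L, nrow(Xtr))), , drop = FALSE]
    cal <- cpp_cnn_calibrate(params, scales, probe, CNN_DROPOUT)
    # arma vectors come back as n x 1 matrices; restore plain vectors
    for (bn in c("b1", "b2", "b3", "b4")) params[[bn]] <- drop(cal[[bn]])
    params$b5 <- cal$b5
    scales <- drop(cal$scales)
  }
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0
  bce <- function(o, yy) -mean(yy * log(pmax(o, 1e-12)) +
                               (1 - yy) * log(pmax(1 - o, 1e-12)))
  loss_trace <- numeric(0)
  best_val <- Inf; best_params <- params; wait <- 0
  nms <- names(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    batch_losses <- numeric(0)
    for (start in seq(1, nrow(Xtr), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, nrow(Xtr))]
      step <- cpp_cnn_train_batch(params, scales,
                                  Xtr[idx, , drop = FALSE], ytr[idx],
                                  CNN_DROPOUT)
      if (!is.finite(step$loss))
        stop("divergence error: non-finite loss at epoch ", ep)
      batch_losses <- c(batch_losses, step$loss)
      grads <- step$grads
      tstep <- tstep + 1
      for (nm in nms) {
        g <- grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        mhat <- mstate[[nm]] / (1 - beta1^tstep)
        vhat <- vstate[[nm]] / (1 - beta2^tstep)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace <- c(loss_trace, mean(batch_losses))
    if (length(val_idx)) {
      val_loss <- bce(cpp_cnn_predict(params, scales, Xval), yval)
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_params <- params
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  }
  model$params <- if (length(val_idx)) best_params else params
  model$scales <- scales
  model$trained <- TRUE
  model$loss_trace <- loss_trace
  model$epochs_run <- length(loss_trace)
  model
}

#' Predicted class-1 probabilities
#'
#' Forward pass with dropout off; deterministic.
#'
#' @param model A `cnn_model`.
#' @param X `N x p` intensity matrix.
#' @return Probabilities in (0, 1).
#' @export
predict_cnn <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  drop(cpp_cnn_predict(model$params, model$scales, X))
}

#' Gradients of the output score with respect to the input
#'
#' Vanilla-gradient attribution: d o / d X_j for every test spectrum and
#' every spectral point, evaluated with dropout off.
#'
#' @param model A `cnn_model`.
#' @param X `N x p` intensity matrix.
#' @return `N x p` matrix of raw score derivatives.
#' @export
cnn_input_gradients <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  cpp_cnn_input_grad(model$params, model$scales, X)
}

#' Vanilla-gradient saliency map with empirical-CDF scaling
#'
#' Computes the raw score derivatives on a test set, then maps every value
#' through the empirical CDF of the pooled set of all derivatives (midranks,
#' so ties share a value; an all-constant gradient field maps to ~0.5).
#' `per_wavenumber = TRUE` instead ranks within each spectral point's column.
#' The summary is the per-wavenumber mean of the CDF values with a 95% normal
#' interval across test spectra.
#'
#' @param model A trained `cnn_model`.
#' @param X Test `N x p` matrix.
#' @param per_wavenumber Rank within columns instead of pooling (default
#'   `FALSE`).
#' @return List with `raw_gradients`, `cdf_values` (both `N x p`), and
#'   `summary` (data.frame: mean, lo95, hi95 per spectral point).
#' @export
vanilla_gradient_saliency <- function(model, X, per_wavenumber = FALSE) {
  if (is.null(dim(X)) || nrow(X) == 0)
    stop("insufficient data: empty test set")
  raw <- cnn_input_gradients(model, X)
  if (per_wavenumber) {
    cdf <- apply(raw, 2, function(col) rank(col) / length(col))
  } else {
    cdf <- matrix(rank(raw) / length(raw), nrow(raw), ncol(raw))
  }
  mu <- colMeans(cdf)
  sem <- apply(cdf, 2, stats::sd) / sqrt(nrow(cdf))
  list(raw_gradients = raw, cdf_values = cdf,
       summary = data.frame(mean = mu, lo95 = mu - 1.96 * sem,
                            hi95 = mu + 1.96 * sem))
}

#' @rdname methods
#' @param epochs,batch_size,lr,validation_split,patience Training controls,
#'   see [train_cnn()].
#' @export
method_cnn <- function(epochs = 50, batch_size = 64, lr = 0.001,
                       validation_split = 0.1, patience = 10) {
  list(name = "CNN",
       fit = function(train, seed = 1L) {
         model <- build_cnn(ncol(train$intensities), seed = seed)
         train_cnn(model, train$intensities, train$labels, epochs = epochs,
                   batch_size = batch_size, lr = lr,
                   validation_split = validation_split, patience = patience,
                   seed = seed)
       },
       score = function(fitted, test) predict_cnn(fitted, test$intensities))
}
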