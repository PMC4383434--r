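#' Fit a min-max scaler onto the sigmoid working range [0.2, 0.8]
#'
#' The perceptron's inputs and targets are kept inside \[0.2, 0.8\] so the
#' sigmoid units never saturate.  The scaler maps each dimension's observed
#' minimum to 0.2 and maximum to 0.8; constant dimensions map to 0.5 and
#' out-of-range query values are clamped into the range.
#'
#' @param x numeric matrix (or vector) of training values.
#' @param lo,hi target range bounds.
#' @return A `range_scaler` object.
#' @export
range_scaler <- function(x, lo = 0.2, hi = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort_dcbr("scaler needs data", "dcbr_argument_error")
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max),
                 lo = lo, hi = hi), class = "range_scaler")
}

#' Scale values into the working range
#'
#' @param values numeric matrix/vector with the scaler's dimensionality.
#' @param scaler a [range_scaler()].
#' @return Scaled values in \[`lo`, `hi`\].
#' @export
scale_to_working_range <- function(values, scaler) {
  v <- as.matrix(values)
  if (ncol(v) != length(scaler$min) && length(scaler$min) == 1L)
    v <- matrix(as.numeric(values), ncol = 1L)
  span <- scaler$max - scaler$min
  out <- v
  for (j in seq_len(ncol(v))) {
    if (span[j] <= 0) out[, j] <- (scaler$lo + scaler$hi) / 2
    else out[, j] <- scaler$lo +
        (v[, j] - scaler$min[j]) / span[j] * (scaler$hi - scaler$lo)
  }
  out[] <- pmin(pmax(out, scaler$lo), scaler$hi)
  if (is.null(dim(values))) drop(out) else out
}

#' Invert the working-range scaling
#'
#' @inheritParams scale_to_working_range
#' @return Values on the original scale (`inverse(scale(x)) = x` on the
#'   training range).
#' @export
inverse_scale <- function(values, scaler) {
  v <- as.matrix(values)
  span <- scaler$max - scaler$min
  out <- v
  for (j in seq_len(ncol(v))) {
    if (span[j] <= 0) out[, j] <- scaler$min[j]
    else out[, j] <- scaler$min[j] +
        (v[, j] - scaler$lo) / (scaler$hi - scaler$lo) * span[j]
  }
  if (is.null(dim(values))) drop(out) else out
}

#' Initialize a one-hidden-layer sigmoid perceptron
#'
#' The hidden layer has `2 * n_in + 1` neurons unless overridden; every
#' neuron carries a bias.  Weights and biases start Uniform(-0.5, 0.5)
#' from `seed`; the momentum state (previous weight deltas) starts at zero.
#'
#' @param n_in,n_out input/output dimensionality (>= 1).
#' @param seed integer seed.
#' @param n_hidden hidden-layer size (default `2 * n_in + 1`).
#' @return An `mlp_model`: `W1` (hidden x in), `b1`, `W2` (out x hidden),
#'   `b2`.
#' @export
#' @examples
#' mlp_init(41, 1, seed = 1)$n_hidden  # 83
mlp_init <- function(n_in, n_out, seed = 1L, n_hidden = 2L * n_in + 1L) {
  if (n_in < 1L || n_out < 1L || n_hidden < 1L)
    abort_dcbr("layer sizes must be >= 1", "dcbr_argument_error")
  with_seed(seed, {
    structure(list(
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out),
      W1 = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
      b1 = stats::runif(n_hidden, -0.5, 0.5),
      W2 = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
      b2 = stats::runif(n_out, -0.5, 0.5),
      trained = FALSE), class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Multilayer perceptron %d-%d-%d (sigmoid, biases)%s\n",
              x$n_in, x$n_hidden, x$n_out,
              if (isTRUE(x$trained)) " [trained]" else ""))
  if (!is.null(x$train_mse))
    cat(sprintf("  final training MSE %.5f after %d epochs\n",
                x$train_mse[length(x$train_mse)], length(x$train_mse)))
  invisible(x)
}

#' Forward pass of the perceptron
#'
#' Hidden activations `sigmoid(W1 x + b1)`, outputs
#' `sigmoid(W2 h + b2)`; all activations lie strictly in (0, 1).
#'
#' @param model an `mlp_model`.
#' @param x input vector or n x n_in matrix.
#' @return Output vector (single input) or n x n_out matrix.
#' @export
mlp_forward <- function(model, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$n_in)
    abort_dcbr(sprintf("input has %d components, model expects %d",
                       ncol(X), model$n_in), "dcbr_shape_error")
  Y <- mlp_forward_cpp(model$W1, model$b1, model$W2, model$b2, X)
  if (single) drop(Y) else Y
}

#' Train the perceptron by online backpropagation with momentum
#'
#' Per-pattern updates: the output-layer delta is
#' `eta * (d - y) * (1 - y) * y * y_hidden` plus `mu` times the previous
#' delta, and the hidden-layer delta backpropagates
#' `sum_k (d_k - y_k)(1 - y_k) y_k w_kj` through the hidden sigmoid
#' derivative; biases update analogously.  With `mu = 0` one update step is
#' exactly a gradient-descent step on half the squared error of that
#' pattern.  Pattern order is reshuffled every epoch from `seed`.  When
#' `validation_fraction > 0`, that share of the patterns is held out and
#' training stops once the validation MSE fails to improve for `patience`
#' epochs (the best weights are kept).
#'
#' @param model an [mlp_init()] model.
#' @param x n x n_in input matrix (pre-scaled into \[0.2, 0.8\]).
#' @param d n x n_out target matrix (pre-scaled into \[0.2, 0.8\]).
#' @param eta learning rate (> 0).
#' @param mu momentum.
#' @param epochs maximum number of epochs.
#' @param seed integer seed for shuffling and the validation split.
#' @param validation_fraction share of patterns held out for early stopping
#'   (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @return The trained `mlp_model` with `train_mse` and `val_mse` traces.
#' @export
mlp_train <- function(model, x, d, eta = 0.1, mu = 0.9, epochs = 1000L,
                      seed = 1L, validation_fraction = 0.2, patience = 50L) {
  if (!is_scalar_number(eta) || eta < 0)
    abort_dcbr("eta must be a nonnegative number", "dcbr_argument_error")
  X <- as.matrix(x)
  D <- if (is.null(dim(d))) matrix(d, ncol = model$n_out) else as.matrix(d)
  if (nrow(X) == 0L) abort_dcbr("no training patterns", "dcbr_argument_error")
  if (ncol(X) != model$n_in || ncol(D) != model$n_out ||
      nrow(X) != nrow(D))
    abort_dcbr("pattern dimensions do not match the model", "dcbr_shape_error")

  with_seed(seed, {
    n <- nrow(X)
    n_val <- if (validation_fraction > 0 && n >= 5L)
      max(1L, floor(validation_fraction * n)) else 0L
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- if (n_val > 0L) idx[-seq_len(n_val)] else idx
    Xtr <- X[tr_idx, , drop = FALSE]; Dtr <- D[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]; Dval <- D[val_idx, , drop = FALSE]
    orders <- matrix(0L, epochs, nrow(Xtr))
    for (e in seq_len(epochs)) orders[e, ] <- sample.int(nrow(Xtr))
    res <- mlp_train_cpp(model$W1, model$b1, model$W2, model$b2,
                         Xtr, Dtr, eta, mu, orders, Xval, Dval,
                         as.integer(patience))
    model$W1 <- res$W1; model$b1 <- res$b1
    model$W2 <- res$W2; model$b2 <- res$b2
    model$train_mse <- res$train_mse
    model$val_mse <- res$val_mse
    model$epochs_run <- res$epochs_run
    model$trained <- TRUE
    model
  })
}

# Regression convenience used by the mixture/CBR layers: scales inputs and
# target into the working range, trains, and predicts in original units.
fit_mlp_regressor <- function(X, y, seed = 1L, eta = 0.1, mu = 0.9,
                              epochs = 300L, validation_fraction = 0.2,
                              patience = 50L, n_hidden = NULL) {
  xsc <- range_scaler(X)
  ysc <- range_scaler(matrix(y, ncol = 1L))
  Xs <- scale_to_working_range(X, xsc)
  ys <- scale_to_working_range(matrix(y, ncol = 1L), ysc)
  net <- mlp_init(ncol(X), 1L, seed = seed,
                  n_hidden = n_hidden %||% (2L * ncol(X) + 1L))
  net <- mlp_train(net, Xs, ys, eta = eta, mu = mu, epochs = epochs,
                   seed = derive_seed(seed, "train"),
                   validation_fraction = validation_fraction,
                   patience = patience)
  structure(list(net = net, xsc = xsc, ysc = ysc), class = "mlp_regressor")
}

#' @export
predict.mlp_regressor <- function(object, newdata, ...) {
  Xs <- scale_to_working_range(as.matrix(newdata), object$xsc)
  out <- mlp_forward(object$net, Xs)
  as.numeric(inverse_scale(matrix(out, ncol = 1L), object$ysc))
}
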