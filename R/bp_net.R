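# Small feedforward back-propagation network used as the classification
# baseline: one hidden layer (two sigmoid units by default), sigmoid output,
# mean-squared-error loss, full-batch gradient descent with a fixed epoch
# budget and seeded weight initialization, so training is deterministic given
# the seed.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the back-propagation baseline network
#'
#' @param X Input matrix (n x p), expected on a normalized `[0, 1]` scale.
#' @param y Binary targets (0/1).
#' @param hidden Number of hidden units (default 2).
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param epochs Full-batch epochs (default 2000).
#' @param seed Integer seed for the uniform `[-0.5, 0.5]` weight
#'   initialization.
#' @return An object of class `pc_bp_net` holding the weights, the training
#'   loss trace endpoints and a `converged` flag (final mean-squared error
#'   below the all-constant-predictor baseline); non-convergence is reported
#'   with a message, never an error.
#' @export
bp_fit <- function(X, y, hidden = 2, learning_rate = 0.1, epochs = 2000, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")

  init <- with_seed(seed, runif((p + 1) * hidden + hidden + 1, -0.5, 0.5))
  W1 <- matrix(init[seq_len(p * hidden)], p, hidden)
  b1 <- init[p * hidden + seq_len(hidden)]
  w2 <- matrix(init[(p + 1) * hidden + seq_len(hidden)], hidden, 1)
  b2 <- init[(p + 1) * hidden + hidden + 1]

  for (e in seq_len(epochs)) {
    A1 <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
    out <- sigmoid(A1 %*% w2 + b2)[, 1]
    d_out <- (2 / n) * (out - y) * out * (1 - out)
    dw2 <- crossprod(A1, d_out)
    db2 <- sum(d_out)
    dA1 <- tcrossprod(d_out, w2[, 1])
    dZ1 <- dA1 * A1 * (1 - A1)
    dW1 <- crossprod(X, dZ1)
    db1 <- colSums(dZ1)
    W1 <- W1 - learning_rate * dW1
    b1 <- b1 - learning_rate * db1
    w2 <- w2 - learning_rate * dw2
    b2 <- b2 - learning_rate * db2
  }
  A1 <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
  out <- sigmoid(A1 %*% w2 + b2)[, 1]
  final_loss <- mean((out - y)^2)
  baseline_loss <- mean((mean(y) - y)^2)
  converged <- final_loss <= baseline_loss + 1e-8
  if (!converged) {
    inform(paste0(
      "bp_fit did not improve on the constant predictor (loss ",
      signif(final_loss, 4), " vs ", signif(baseline_loss, 4), ")"
    ))
  }
  structure(
    list(
      W1 = W1, b1 = b1, w2 = w2, b2 = b2,
      final_loss = final_loss, converged = converged,
      hidden = hidden, learning_rate = learning_rate, epochs = epochs, seed = seed
    ),
    class = "pc_bp_net"
  )
}

#' Predict with the back-propagation baseline network
#'
#' @param net A `pc_bp_net` object.
#' @param X Input matrix on the training scale.
#' @return Numeric outputs in `(0, 1)`; classify with `>= 0.5`.
#' @export
bp_predict <- function(net, X) {
  X <- as.matrix(X)
  A1 <- sigmoid(sweep(X %*% net$W1, 2, net$b1, "+"))
  as.numeric(sigmoid(A1 %*% net$w2 + net$b2))
}
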