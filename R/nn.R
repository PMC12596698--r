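# Feed-forward network internals: parameter layout, forward pass, losses,
# backpropagation and the Adam optimizer. The parameter layout is the
# contract the swarm optimizer relies on, so it is fixed and documented:
# layers in input->output order; within a layer, the weight matrix
# (fan_in x fan_out) in R's column-major order, then the bias vector.

#' Define a network architecture
#'
#' All base models share one architecture (three hidden layers of 512, 256
#' and 128 units by default); the stacking network uses a smaller one (64,
#' 32). The output activation must match the task: `softmax` for multiclass,
#' `sigmoid` for binary/multilabel, `identity` for regression.
#'
#' @param input_dim Length of the combined input vector.
#' @param hidden_dims Integer vector of hidden-layer widths.
#' @param output_dim Label dimension (number of classes/labels, or 1).
#' @param output_activation `"softmax"`, `"sigmoid"` or `"identity"`.
#' @param hidden_activation Hidden nonlinearity; only `"relu"` is provided.
#' @return An object of class `network_architecture`.
#' @export
network_architecture <- function(input_dim, hidden_dims = c(512L, 256L, 128L),
                                 output_dim,
                                 output_activation = c("softmax", "sigmoid", "identity"),
                                 hidden_activation = "relu") {
  output_activation <- match.arg(output_activation)
  dims <- c(input_dim, hidden_dims, output_dim)
  if (any(dims < 1) || any(dims != round(dims)))
    err_invalid_config("all layer widths must be positive integers")
  if (hidden_activation != "relu")
    err_invalid_config("unsupported hidden activation '%s'", hidden_activation)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 output_dim = as.integer(output_dim),
                 output_activation = output_activation,
                 hidden_activation = hidden_activation),
            class = "network_architecture")
}

#' @export
print.network_architecture <- function(x, ...) {
  cat(sprintf("<network_architecture> %d -> %s -> %d (%s)\n", x$input_dim,
              paste(x$hidden_dims, collapse = "/"), x$output_dim,
              x$output_activation))
  invisible(x)
}

layer_dims <- function(arch) {
  c(arch$input_dim, arch$hidden_dims, arch$output_dim)
}

#' Number of learnable parameters of an architecture
#'
#' Sum over consecutive layer pairs of `fan_in * fan_out + fan_out`.
#'
#' @param architecture A [network_architecture()].
#' @return Integer parameter count.
#' @export
param_count <- function(architecture) {
  d <- layer_dims(architecture)
  sum(d[-length(d)] * d[-1] + d[-1])
}

# Fresh parameter list under the current RNG state: each weight uniform on
# +/- 1/sqrt(fan_in) (fan-in scaling), biases zero.
init_layer_params <- function(arch) {
  d <- layer_dims(arch)
  lapply(seq_len(length(d) - 1), function(i) {
    s <- 1 / sqrt(d[i])
    list(W = matrix(stats::runif(d[i] * d[i + 1], -s, s), d[i], d[i + 1]),
         b = rep(0, d[i + 1]))
  })
}

flatten_layer_params <- function(params) {
  unlist(lapply(params, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

unflatten_layer_params <- function(vec, arch) {
  d <- layer_dims(arch)
  expected <- param_count(arch)
  if (length(vec) != expected)
    err_invalid_input("parameter vector length mismatch: expected %d, received %d",
                      expected, length(vec))
  out <- vector("list", length(d) - 1)
  pos <- 0L
  for (i in seq_len(length(d) - 1)) {
    nw <- d[i] * d[i + 1]
    out[[i]] <- list(W = matrix(vec[pos + seq_len(nw)], d[i], d[i + 1]),
                     b = vec[pos + nw + seq_len(d[i + 1])])
    pos <- pos + nw + d[i + 1]
  }
  out
}

apply_output_activation <- function(Z, activation) {
  switch(activation,
    softmax = {
      Z <- Z - apply(Z, 1, max)            # numerical stability
      E <- exp(Z)
      E / rowSums(E)
    },
    sigmoid = stats::plogis(Z),
    identity = Z)
}

# Forward pass. Returns the output scores; with keep = TRUE also the
# per-layer activations needed by backprop.
nn_forward <- function(params, X, arch, keep = FALSE) {
  A <- list(X)
  H <- X
  L <- length(params)
  for (i in seq_len(L - 1)) {
    H <- H %*% params[[i]]$W
    H <- sweep(H, 2, params[[i]]$b, `+`)
    H[H < 0] <- 0                           # relu
    if (keep) A[[i + 1]] <- H
  }
  Z <- sweep(H %*% params[[L]]$W, 2, params[[L]]$b, `+`)
  P <- apply_output_activation(Z, arch$output_activation)
  if (keep) list(P = P, A = A) else P
}

# Mean loss over samples. Y is a numeric matrix matching P's shape
# (one-hot for multiclass).
nn_loss <- function(P, Y, loss) {
  eps <- 1e-12
  switch(loss,
    "cross-entropy" = -mean(rowSums(Y * log(pmax(P, eps)))),
    "binary cross-entropy" =
      -mean(Y * log(pmax(P, eps)) + (1 - Y) * log(pmax(1 - P, eps))),
    "mse" = mean((P - Y)^2),
    err_invalid_config("unknown loss '%s'", loss))
}

# Gradient of the mean loss w.r.t. every W and b. For the matched
# activation/loss pairs (softmax + cross-entropy, sigmoid + BCE) the output
# delta collapses to (P - Y) / n (scaled by 1/output_dim where the loss
# averages over entries).
nn_gradients <- function(params, X, Y, arch, loss) {
  fw <- nn_forward(params, X, arch, keep = TRUE)
  n <- nrow(X)
  delta <- switch(loss,
    "cross-entropy" = (fw$P - Y) / n,
    "binary cross-entropy" = (fw$P - Y) / (n * ncol(Y)),
    "mse" = {
      d0 <- 2 * (fw$P - Y) / (n * ncol(Y))
      if (arch$output_activation == "sigmoid") d0 * fw$P * (1 - fw$P) else d0
    })
  L <- length(params)
  grads <- vector("list", L)
  for (i in L:1) {
    grads[[i]] <- list(W = crossprod(fw$A[[i]], delta), b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(params[[i]]$W)
      delta[fw$A[[i]] <= 0] <- 0            # relu derivative
    }
  }
  list(grads = grads, loss_value = nn_loss(fw$P, Y, loss))
}

# Mini-batch Adam. Deterministic under `seed` (batch shuffling is the only
# randomness). Returns updated params plus the per-epoch mean training loss.
nn_train <- function(params, X, Y, arch, loss, epochs, batch_size,
                     learning_rate, seed = NULL) {
  if (epochs == 0)
    return(list(params = params, history = numeric(0)))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  mstate <- lapply(params, function(l)
    list(W = array(0, dim(l$W)), b = numeric(length(l$b))))
  vstate <- mstate
  tstep <- 0L
  n <- nrow(X)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1, n)]
        g <- nn_gradients(params, X[rows, , drop = FALSE],
                          Y[rows, , drop = FALSE], arch, loss)
        ep_loss <- ep_loss + g$loss_value * length(rows)
        tstep <- tstep + 1L
        corr1 <- 1 - beta1^tstep
        corr2 <- 1 - beta2^tstep
        for (i in seq_along(params)) {
          mstate[[i]]$W <- beta1 * mstate[[i]]$W + (1 - beta1) * g$grads[[i]]$W
          vstate[[i]]$W <- beta2 * vstate[[i]]$W + (1 - beta2) * g$grads[[i]]$W^2
          mstate[[i]]$b <- beta1 * mstate[[i]]$b + (1 - beta1) * g$grads[[i]]$b
          vstate[[i]]$b <- beta2 * vstate[[i]]$b + (1 - beta2) * g$grads[[i]]$b^2
          params[[i]]$W <- params[[i]]$W - learning_rate *
            (mstate[[i]]$W / corr1) / (sqrt(vstate[[i]]$W / corr2) + adam_eps)
          params[[i]]$b <- params[[i]]$b - learning_rate *
            (mstate[[i]]$b / corr1) / (sqrt(vstate[[i]]$b / corr2) + adam_eps)
        }
      }
      history[ep] <- ep_loss / n
      if (!is.finite(history[ep]))
        err_numerical("non-finite training loss at epoch %d", ep)
    }
  })
  list(params = params, history = history)
}
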