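#' Architecture of a two-hidden-layer feedforward classifier
#'
#' A `network_spec` fixes the four layer widths of the classifier:
#' input, two tanh hidden layers, and a softmax output layer. Data flow
#' is strictly feedforward, input -> hidden 1 -> hidden 2 -> output, with
#' no recurrent connections.
#'
#' @param n_inputs Length of the input vector (positive integer).
#' @param layer1,layer2 Hidden-layer widths (positive integers), usually
#'   from [huang_layer_sizes()].
#' @param n_outputs Number of classes (positive integer).
#' @return An object of class `"network_spec"`.
#' @examples
#' network_spec(6003, 260, 156, 6)
#' @export
network_spec <- function(n_inputs, layer1, layer2, n_outputs) {
  spec <- list(
    n_inputs = check_count(n_inputs, "n_inputs"),
    layer1 = check_count(layer1, "layer1"),
    layer2 = check_count(layer2, "layer2"),
    n_outputs = check_count(n_outputs, "n_outputs"),
    hidden_activation = "tanh",
    output_activation = "softmax"
  )
  class(spec) <- "network_spec"
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "Two-hidden-layer feedforward spec: %d -> %d -> %d -> %d (tanh/tanh/softmax)\n",
    x$n_inputs, x$layer1, x$layer2, x$n_outputs))
  invisible(x)
}

n_parameters <- function(spec) {
  with(spec, layer1 * n_inputs + layer1 +
         layer2 * layer1 + layer2 +
         n_outputs * layer2 + n_outputs)
}

#' Initialize network weights
#'
#' Weights are drawn uniformly in \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}
#' per layer (which keeps early tanh activations in their linear range);
#' biases start at zero. Deterministic given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A list of class `"network_weights"` with weight matrices
#'   `W1` (layer1 x n_inputs), `W2` (layer2 x layer1),
#'   `W3` (n_outputs x layer2) and bias vectors `b1`, `b2`, `b3`.
#' @examples
#' w <- init_network(network_spec(2, 3, 2, 2), seed = 1)
#' dim(w$W1) # 3 2
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- list(W1 = c(spec$layer1, spec$n_inputs),
               W2 = c(spec$layer2, spec$layer1),
               W3 = c(spec$n_outputs, spec$layer2))
  w <- with_seed(seed, {
    lapply(dims, function(d) {
      lim <- sqrt(6 / (d[1] + d[2]))
      matrix(runif(d[1] * d[2], -lim, lim), d[1], d[2])
    })
  })
  w$b1 <- numeric(spec$layer1)
  w$b2 <- numeric(spec$layer2)
  w$b3 <- numeric(spec$n_outputs)
  w$spec <- spec
  class(w) <- "network_weights"
  w
}

# Flatten weights to one parameter vector and back (optimizers work on
# the flat vector; order W1,b1,W2,b2,W3,b3).
flatten_weights <- function(w) {
  c(as.numeric(w$W1), w$b1, as.numeric(w$W2), w$b2, as.numeric(w$W3), w$b3)
}

unflatten_weights <- function(par, spec) {
  take <- function(n) {
    out <- par[seq_len(n)]
    par <<- par[-seq_len(n)]
    out
  }
  w <- list(
    W1 = matrix(take(spec$layer1 * spec$n_inputs), spec$layer1, spec$n_inputs),
    b1 = NULL, W2 = NULL, b2 = NULL, W3 = NULL, b3 = NULL)
  w$b1 <- take(spec$layer1)
  w$W2 <- matrix(take(spec$layer2 * spec$layer1), spec$layer2, spec$layer1)
  w$b2 <- take(spec$layer2)
  w$W3 <- matrix(take(spec$n_outputs * spec$layer2), spec$n_outputs, spec$layer2)
  w$b3 <- take(spec$n_outputs)
  w$spec <- spec
  class(w) <- "network_weights"
  w
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Batched forward pass. X is n x n_inputs; returns list with hidden
# activations (kept for backprop) and probability matrix P (n x classes).
forward_pass <- function(w, X) {
  H1 <- tanh(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  H2 <- tanh(sweep(H1 %*% t(w$W2), 2L, w$b2, "+"))
  Z <- sweep(H2 %*% t(w$W3), 2L, w$b3, "+")
  list(H1 = H1, H2 = H2, P = softmax_rows(Z))
}

#' Forward pass: class probabilities for one input
#'
#' Computes `softmax(W3 tanh(W2 tanh(W1 x + b1) + b2) + b3)`, a
#' probability vector over the output classes (entries in (0,1), summing
#' to 1).
#'
#' @param weights A `"network_weights"` object from [init_network()].
#' @param input Numeric vector of length `n_inputs` (or a matrix with
#'   one row per case).
#' @return A probability vector of length `n_outputs` (or a matrix with
#'   one probability row per input row).
#' @examples
#' w <- init_network(network_spec(2, 3, 2, 2), seed = 1)
#' ffnet_forward(w, c(0.1, -0.2))
#' @export
ffnet_forward <- function(weights, input) {
  stopifnot(inherits(weights, "network_weights"))
  spec <- weights$spec
  vec <- is.null(dim(input))
  X <- if (vec) matrix(input, nrow = 1L) else as.matrix(input)
  if (ncol(X) != spec$n_inputs) {
    stop_domain(sprintf("input has %d features; the network expects %d",
                        ncol(X), spec$n_inputs))
  }
  if (!all(is.finite(X))) stop_domain("input contains non-finite values")
  P <- forward_pass(weights, X)$P
  if (vec) drop(P) else P
}

check_batch <- function(weights, inputs, targets) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) == 0L) stop_domain("empty batch")
  spec <- weights$spec
  if (ncol(inputs) != spec$n_inputs || ncol(targets) != spec$n_outputs ||
      nrow(inputs) != nrow(targets)) {
    stop_domain("batch dimensions do not match the network spec")
  }
  if (!all(targets %in% c(0, 1)) || !all(rowSums(targets) == 1)) {
    stop_domain("targets must be one-hot rows")
  }
  list(inputs = inputs, targets = targets)
}

#' Cross-entropy loss of a network on a labeled batch
#'
#' Mean over cases of \eqn{-\sum_k y_k \log p_k} with one-hot targets
#' `y` and forward-pass probabilities `p`. Strictly positive for finite
#' weights.
#'
#' @param weights A `"network_weights"` object.
#' @param inputs Case-by-feature matrix.
#' @param targets One-hot target matrix (one row per case).
#' @return A single non-negative number.
#' @seealso [ffnet_gradient()] for its exact gradient.
#' @export
ffnet_loss <- function(weights, inputs, targets) {
  b <- check_batch(weights, inputs, targets)
  P <- forward_pass(weights, b$inputs)$P
  # clamp away from 0 so a confidently wrong prediction yields a large
  # finite loss rather than Inf
  -mean(log(pmax(rowSums(P * b$targets), 1e-300)))
}

#' Exact gradient of the cross-entropy loss
#'
#' Reverse-mode (backpropagation) gradient of [ffnet_loss()] with
#' respect to every weight and bias; agrees with central finite
#' differences to high relative precision.
#'
#' @inheritParams ffnet_loss
#' @return A list shaped like the weights (`W1`, `b1`, `W2`, `b2`,
#'   `W3`, `b3`), each entry the partial derivative of the mean loss.
#' @export
ffnet_gradient <- function(weights, inputs, targets) {
  b <- check_batch(weights, inputs, targets)
  X <- b$inputs
  n <- nrow(X)
  fw <- forward_pass(weights, X)
  D3 <- (fw$P - b$targets) / n              # n x n_outputs
  D2 <- (D3 %*% weights$W3) * (1 - fw$H2^2) # n x layer2
  D1 <- (D2 %*% weights$W2) * (1 - fw$H1^2) # n x layer1
  list(W1 = t(D1) %*% X, b1 = colSums(D1),
       W2 = t(D2) %*% fw$H1, b2 = colSums(D2),
       W3 = t(D3) %*% fw$H2, b3 = colSums(D3))
}

# Flat-vector loss/gradient closures used by the optimizers.
loss_grad_closures <- function(spec, X, Y) {
  list(
    fn = function(par) ffnet_loss(unflatten_weights(par, spec), X, Y),
    gr = function(par) {
      g <- ffnet_gradient(unflatten_weights(par, spec), X, Y)
      c(as.numeric(g$W1), g$b1, as.numeric(g$W2), g$b2, as.numeric(g$W3), g$b3)
    }
  )
}
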