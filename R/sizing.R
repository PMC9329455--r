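#' Closed-form hidden-layer sizes for a two-hidden-layer classifier
#'
#' Huang's construction guarantees that a feedforward network with two
#' hidden layers can learn `N` distinct samples with `m` output neurons
#' when the first hidden layer has \eqn{\sqrt{(m+2)N} + 2\sqrt{N/(m+2)}}
#' neurons and the second \eqn{m\sqrt{N/(m+2)}}. `huang_raw_sizes()`
#' returns the real-valued formula values; `huang_layer_sizes()` rounds
#' each up to a whole neuron count (ceiling), which is the size actually
#' used to build a network.
#'
#' For the T-maze problem (`n_samples = 5400`, `n_outputs = 6`) the raw
#' sizes are 259.81 and 155.88, giving layers of 260 and 156 neurons; for
#' the EEG independent-component problem (`n_samples = 1632`,
#' `n_outputs = 2`) they are 121.19 and 40.40, giving 122 and 41.
#'
#' @param n_samples Number of distinct training samples, `N` (positive
#'   integer).
#' @param n_outputs Number of output neurons / classes, `m` (positive
#'   integer).
#' @return `huang_raw_sizes()`: a named numeric vector
#'   `c(layer1 = ..., layer2 = ...)` of positive reals.
#'   `huang_layer_sizes()`: the same, as positive integers (ceilings of
#'   the raw sizes).
#' @examples
#' huang_raw_sizes(5400, 6)   # 259.81, 155.88
#' huang_layer_sizes(5400, 6) # 260, 156
#' @export
huang_raw_sizes <- function(n_samples, n_outputs) {
  n_samples <- check_count(n_samples, "n_samples")
  n_outputs <- check_count(n_outputs, "n_outputs")
  N <- as.numeric(n_samples)
  m <- as.numeric(n_outputs)
  c(layer1 = sqrt((m + 2) * N) + 2 * sqrt(N / (m + 2)),
    layer2 = m * sqrt(N / (m + 2)))
}

#' @rdname huang_raw_sizes
#' @export
huang_layer_sizes <- function(n_samples, n_outputs) {
  raw <- huang_raw_sizes(n_samples, n_outputs)
  out <- as.integer(ceiling(raw))
  names(out) <- names(raw)
  out
}
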