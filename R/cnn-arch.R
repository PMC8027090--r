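#' Describe the one-dimensional CNN architecture
#'
#' The network is `I1(1xN) - C2(i2 x 1 x n2) - C3(i3 x 1 x n3) - F4 - O5`:
#' an input row of length `N`, two valid (no-padding) 1-D convolutional
#' layers with ReLU activations, a fully connected tanh layer (F4, with
#' dropout during training) and a softmax output layer (O5) over two
#' classes. Optional non-overlapping pooling (max or average) can be enabled
#' after each convolution; it is disabled by default because the input rows
#' are short.
#'
#' For the default CSP input (`N = 4`) the kernels must be tiny: with two
#' length-2 kernels the spatial chain is 4 -> 3 -> 2, the shortest valid
#' two-layer chain that keeps every feature-map length at least 1.
#'
#' @param input_length Length `N` of the input row.
#' @param n_kernels Integer vector: kernels per conv layer (default `c(8, 16)`).
#' @param kernel_lengths Integer vector of 1-D kernel lengths (default
#'   `c(2, 2)`).
#' @param pool_widths Pooling window per conv layer; 1 disables (default).
#' @param pool_modes `"max"` or `"average"` per conv layer.
#' @param dense_width Units in F4 (default 32).
#' @param n_classes Output classes (fixed at 2).
#' @param loss `"sse"` (squared error on softmax outputs, default) or
#'   `"cross_entropy"`.
#' @return Object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(input_length,
                             n_kernels = c(8L, 16L),
                             kernel_lengths = c(2L, 2L),
                             pool_widths = rep(1L, length(n_kernels)),
                             pool_modes = rep("max", length(n_kernels)),
                             dense_width = 32L,
                             n_classes = 2L,
                             loss = c("sse", "cross_entropy")) {
  if (length(n_kernels) != length(kernel_lengths) ||
      length(n_kernels) != length(pool_widths) ||
      length(n_kernels) != length(pool_modes))
    mi_config_error("conv layer descriptions must have equal length")
  if (n_classes != 2L) mi_config_error("the network is two-class (O5 = 2)")
  if (!all(pool_modes %in% c("max", "average")))
    mi_config_error("pool_modes must be 'max' or 'average'")
  arch <- structure(list(input_length = as.integer(input_length),
                         n_kernels = as.integer(n_kernels),
                         kernel_lengths = as.integer(kernel_lengths),
                         pool_widths = as.integer(pool_widths),
                         pool_modes = pool_modes,
                         dense_width = as.integer(dense_width),
                         n_classes = 2L,
                         loss = match.arg(loss)),
                    class = "cnn_architecture")
  sizes <- conv_chain_lengths(arch)
  if (any(sizes < 1))
    mi_config_error(sprintf(
      "convolution/pooling chain collapses below length 1 (lengths: %s)",
      paste(sizes, collapse = " -> ")))
  arch
}

# Feature-map length after each conv(+pool) layer; first element is N.
conv_chain_lengths <- function(arch) {
  len <- arch$input_length
  out <- len
  for (l in seq_along(arch$n_kernels)) {
    len <- len - arch$kernel_lengths[l] + 1L
    if (len >= 1 && arch$pool_widths[l] > 1)
      len <- len %/% arch$pool_widths[l]
    out <- c(out, len)
  }
  out
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> I1(1x%d)", x$input_length))
  for (l in seq_along(x$n_kernels))
    cat(sprintf(" - C%d(%dx1x%d%s)", l + 1, x$n_kernels[l],
                x$kernel_lengths[l],
                if (x$pool_widths[l] > 1)
                  sprintf(", %s pool %d", x$pool_modes[l], x$pool_widths[l])
                else ""))
  cat(sprintf(" - F4(%d) - O5(%d), loss=%s\n", x$dense_width, x$n_classes,
              x$loss))
  invisible(x)
}

#' Initialize network parameters
#'
#' Convolution kernels are drawn uniformly from `[-0.3, +0.3]`; fully
#' connected weights are normal with standard deviation 0.1, truncated to
#' the same interval; every bias is the constant 0.1. Reproducible from
#' `seed`.
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed.
#' @return Object of class `cnn_parameters`: `conv` (list of `W`
#'   `[K, D, F]` arrays and `b` length-K vectors) and `dense` (list of `W`
#'   `[in, out]` matrices and `b` vectors) in layer order F4, O5.
#' @export
init_parameters <- function(arch, seed = 1L) {
  set.seed(as.integer(seed))
  depth <- 1L
  conv <- vector("list", length(arch$n_kernels))
  for (l in seq_along(arch$n_kernels)) {
    K <- arch$n_kernels[l]; F <- arch$kernel_lengths[l]
    conv[[l]] <- list(W = array(stats::runif(K * depth * F, -0.3, 0.3),
                                c(K, depth, F)),
                      b = rep(0.1, K))
    depth <- K
  }
  flat <- arch$n_kernels[length(arch$n_kernels)] *
    conv_chain_lengths(arch)[length(arch$n_kernels) + 1]
  dense_dims <- list(c(flat, arch$dense_width),
                     c(arch$dense_width, arch$n_classes))
  dense <- lapply(dense_dims, function(d)
    list(W = matrix(truncated_normal(prod(d), sd = 0.1, bound = 0.3),
                    d[1], d[2]),
         b = rep(0.1, d[2])))
  structure(list(conv = conv, dense = dense), class = "cnn_parameters")
}

# Normal(0, sd) truncated to [-bound, bound] by resampling.
truncated_normal <- function(n, sd, bound) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > bound)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > bound]
  }
  x
}

#' Training hyperparameters
#'
#' Defaults follow the training recipe: mini-batches of 64, 150 epochs, a
#' learning rate decaying exponentially from 0.02 toward 0.0002 with decay
#' speed 1000 iterations, and dropout rate 0.5 at F4. `n_iterations`, when
#' given, caps the total number of mini-batch steps regardless of epochs.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Passes over the training set.
#' @param lr_start,lr_end,decay_speed Learning-rate schedule; see [lr_at()].
#' @param dropout_rate Probability of zeroing each F4 unit during training.
#' @param seed Integer seed for shuffling, dropout and initialization.
#' @param n_iterations Optional cap on mini-batch iterations.
#' @param log_every Learning-curve logging interval in iterations.
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 64L, epochs = 150L,
                            lr_start = 0.02, lr_end = 0.0002,
                            decay_speed = 1000, dropout_rate = 0.5,
                            seed = 1L, n_iterations = NULL,
                            log_every = 100L) {
  if (lr_end <= 0 || lr_end >= lr_start)
    mi_config_error("need 0 < lr_end < lr_start")
  if (dropout_rate < 0 || dropout_rate >= 1)
    mi_config_error("dropout_rate must lie in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_start = lr_start, lr_end = lr_end,
                 decay_speed = decay_speed,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed),
                 n_iterations = if (!is.null(n_iterations))
                   as.integer(n_iterations),
                 log_every = as.integer(log_every)),
            class = "training_config")
}

#' Learning rate at a given iteration
#'
#' `eta(i) = lr_end + (lr_start - lr_end) * exp(-i / decay_speed)`:
#' monotone decreasing from `lr_start` at iteration 0 toward `lr_end`.
#'
#' @param iteration Nonnegative iteration index (vectorized).
#' @param config A [training_config()].
#' @return Learning rate(s).
#' @export
lr_at <- function(iteration, config) {
  if (any(iteration < 0)) mi_input_error("iteration must be >= 0")
  config$lr_end + (config$lr_start - config$lr_end) *
    exp(-iteration / config$decay_speed)
}

#' Inverted dropout mask
#'
#' Draws a Bernoulli(`1 - rate`) keep mask of the requested shape; kept
#' entries carry the value `1 / (1 - rate)` so that the expected activation
#' is unchanged and inference needs no rescaling.
#'
#' @param dims Integer vector of dimensions.
#' @param rate Drop probability in `[0, 1)`.
#' @return Numeric array with entries `0` or `1 / (1 - rate)`.
#' @export
dropout_mask <- function(dims, rate) {
  if (rate < 0 || rate >= 1) mi_input_error("rate must lie in [0, 1)")
  keep <- stats::rbinom(prod(dims), 1, 1 - rate)
  array(keep / (1 - rate), dims)
}
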