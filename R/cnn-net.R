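# Internal batched tensor layout: conv activations are [batch, depth, length]
# arrays; flattening to the dense layers is column-major (depth fastest),
# matched exactly by the backward pass.

conv_forward_batch <- function(x, W, b, activation = "relu") {
  B <- dim(x)[1]; D <- dim(x)[2]; L <- dim(x)[3]
  K <- dim(W)[1]; Fk <- dim(W)[3]
  if (dim(W)[2] != D)
    mi_shape_error("kernel depth does not match input depth")
  Lo <- L - Fk + 1
  if (Lo < 1) mi_shape_error("input is shorter than the kernel")
  Wm <- matrix(W, nrow = K)                    # K x (D*Fk), depth fastest
  net <- array(0, c(B, K, Lo))
  bB <- matrix(b, B, K, byrow = TRUE)
  for (j in seq_len(Lo)) {
    Xj <- matrix(x[, , j:(j + Fk - 1), drop = FALSE], nrow = B)
    net[, , j] <- Xj %*% t(Wm) + bB
  }
  act <- if (activation == "relu") pmax(net, 0) else net
  list(net = net, act = act)
}

conv_backward_batch <- function(delta_net, x_in, W) {
  B <- dim(x_in)[1]; Lo <- dim(delta_net)[3]
  K <- dim(W)[1]; Fk <- dim(W)[3]
  Wm <- matrix(W, nrow = K)
  dWm <- matrix(0, K, ncol(Wm))
  db <- numeric(K)
  din <- array(0, dim(x_in))
  for (j in seq_len(Lo)) {
    Dj <- matrix(delta_net[, , j], B, K)
    Xj <- matrix(x_in[, , j:(j + Fk - 1), drop = FALSE], nrow = B)
    dWm <- dWm + t(Dj) %*% Xj
    db <- db + colSums(Dj)
    din[, , j:(j + Fk - 1)] <- din[, , j:(j + Fk - 1), drop = FALSE] +
      array(Dj %*% Wm, c(B, dim(x_in)[2], Fk))
  }
  list(dW = array(dWm, dim(W)), db = db, din = din)
}

pool_forward_batch <- function(x, width, mode) {
  B <- dim(x)[1]; K <- dim(x)[2]; L <- dim(x)[3]
  nw <- L %/% width
  if (nw < 1) mi_shape_error("pooling window wider than the feature map")
  xa <- array(x[, , seq_len(nw * width), drop = FALSE], c(B, K, width, nw))
  M <- matrix(aperm(xa, c(1, 2, 4, 3)), ncol = width)  # rows: (b,k,win)
  if (mode == "max") {
    idx <- max.col(M, ties.method = "first")           # ties -> lowest index
    out <- array(M[cbind(seq_len(nrow(M)), idx)], c(B, K, nw))
    argmax <- array(idx, c(B, K, nw))
  } else {
    out <- array(rowMeans(M), c(B, K, nw))
    argmax <- NULL
  }
  list(out = out,
       trace = list(width = width, mode = mode, in_dims = dim(x),
                    n_windows = nw, argmax = argmax))
}

pool_backward_batch <- function(delta, trace) {
  width <- trace$width; nw <- trace$n_windows
  B <- trace$in_dims[1]; K <- trace$in_dims[2]; L <- trace$in_dims[3]
  Md <- matrix(0, B * K * nw, width)
  dv <- as.numeric(delta)
  if (trace$mode == "max") {
    Md[cbind(seq_along(dv), as.numeric(trace$argmax))] <- dv
  } else {
    Md[] <- dv / width                                 # recycles down columns
  }
  din <- array(0, c(B, K, L))
  din[, , seq_len(nw * width)] <-
    aperm(array(Md, c(B, K, nw, width)), c(1, 2, 4, 3))
  din
}

#' Valid 1-D convolutional layer forward pass (ReLU)
#'
#' Cross-correlates a `depth x length` input with `K` kernels of shape
#' `depth x kernel_length` (no padding), adds each kernel's bias and applies
#' the ReLU. Output length is `length - kernel_length + 1`.
#'
#' @param input Numeric vector (depth 1) or `depth x length` matrix.
#' @param kernels Numeric vector (one depth-1 kernel), `K x kernel_length`
#'   matrix (depth 1), or `[K, depth, kernel_length]` array.
#' @param bias Length-`K` bias vector (recycled if scalar).
#' @param activation `"relu"` (default) or `"linear"`.
#' @return List with `feature_maps` (`K x out_length`) and
#'   `pre_activations` of the same shape.
#' @export
#' @examples
#' conv_forward(c(1, 2, 3), c(1, 1), 0)$feature_maps   # 3 5
conv_forward <- function(input, kernels, bias, activation = "relu") {
  if (is.vector(input)) input <- matrix(input, nrow = 1)
  if (is.vector(kernels)) kernels <- array(kernels, c(1, 1, length(kernels)))
  if (is.matrix(kernels))
    kernels <- array(kernels, c(nrow(kernels), 1, ncol(kernels)))
  K <- dim(kernels)[1]
  bias <- rep_len(bias, K)
  x <- array(0, c(1, nrow(input), ncol(input)))
  x[1, , ] <- input
  cf <- conv_forward_batch(x, kernels, bias, activation)
  list(feature_maps = matrix(cf$act[1, , ], K),
       pre_activations = matrix(cf$net[1, , ], K))
}

#' Fully connected layer forward pass
#'
#' `tanh(x W + b)` for the hidden layer, or softmax over the class scores
#' `x W + b` for the output layer.
#'
#' @param x Input vector, or matrix with one row per sample.
#' @param W Weight matrix `[in, out]`.
#' @param b Bias vector of length `out`.
#' @param activation `"tanh"` or `"softmax"`.
#' @return Output with the same orientation as `x`.
#' @export
dense_forward <- function(x, W, b, activation = c("tanh", "softmax")) {
  activation <- match.arg(activation)
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(W) || length(b) != ncol(W))
    mi_shape_error("dense layer shape mismatch")
  z <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  y <- if (activation == "tanh") tanh(z) else softmax_rows(z)
  if (vec) drop(y) else y
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Sum-of-squared-errors loss on class probabilities
#'
#' `Error = sum_i (Y_i - R_i)^2` between predicted probabilities and a
#' one-hot target. For matrix inputs (one sample per row) the mean
#' per-sample error is returned.
#'
#' @param Y Predicted probability vector or matrix.
#' @param R One-hot target of the same shape.
#' @return Nonnegative scalar.
#' @export
sse_loss <- function(Y, R) {
  if (!identical(dim(Y) %||% length(Y), dim(R) %||% length(R)))
    mi_shape_error("Y and R must have identical shape")
  if (is.matrix(Y)) mean(rowSums((Y - R)^2)) else sum((Y - R)^2)
}

#' Full network forward pass
#'
#' Runs a batch of input rows through the conv stack, flattening, F4 (tanh,
#' with inverted dropout when `training = TRUE`) and the softmax output
#' layer, recording every pre-activation, activation and dropout mask so
#' that [cnn_backward()] can replay the pass.
#'
#' @param params A [init_parameters()] result.
#' @param arch The matching [cnn_architecture()].
#' @param x Numeric matrix `[batch, input_length]` (a vector is one sample).
#' @param training Apply dropout? (Uses the current RNG stream.)
#' @param dropout_rate Drop probability at F4 when training.
#' @return A forward trace: list with `probs` (`[batch, 2]` softmax output)
#'   and the per-layer records.
#' @export
cnn_forward <- function(params, arch, x, training = FALSE,
                        dropout_rate = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != arch$input_length)
    mi_shape_error(sprintf("input length %d does not match N = %d",
                           ncol(x), arch$input_length))
  B <- nrow(x)
  a <- array(0, c(B, 1, ncol(x)))
  a[, 1, ] <- x
  convs <- vector("list", length(params$conv))
  for (l in seq_along(params$conv)) {
    cf <- conv_forward_batch(a, params$conv[[l]]$W, params$conv[[l]]$b)
    rec <- list(x_in = a, net = cf$net)
    out <- cf$act
    if (arch$pool_widths[l] > 1) {
      pf <- pool_forward_batch(out, arch$pool_widths[l], arch$pool_modes[l])
      rec$pool <- pf$trace
      out <- pf$out
    }
    convs[[l]] <- rec
    a <- out
  }
  flat <- matrix(a, nrow = B)
  z1 <- flat %*% params$dense[[1]]$W +
    matrix(params$dense[[1]]$b, B, arch$dense_width, byrow = TRUE)
  y1 <- tanh(z1)
  mask <- NULL
  y1d <- y1
  if (training && dropout_rate > 0) {
    mask <- dropout_mask(dim(y1), dropout_rate)
    y1d <- y1 * mask
  }
  z2 <- y1d %*% params$dense[[2]]$W +
    matrix(params$dense[[2]]$b, B, arch$n_classes, byrow = TRUE)
  probs <- softmax_rows(z2)
  list(probs = probs, convs = convs, flat = flat,
       z1 = z1, y1 = y1, mask = mask, y1d = y1d, z2 = z2,
       conv_out_dims = dim(a))
}

#' Backpropagate errors and accumulate parameter gradients
#'
#' Propagates the output error through the softmax head (squared-error loss
#' by default, cross-entropy if the architecture says so), the tanh dense
#' layer (through the recorded dropout mask), the flattening, any pooling
#' layers (max deltas routed to the recorded argmax, average deltas split
#' evenly) and the convolution stack (full convolution with flipped kernels
#' times the ReLU derivative). Weight gradients correlate the deltas with
#' the layer inputs; bias gradients sum the deltas. Gradients are averaged
#' over the batch.
#'
#' @param trace A [cnn_forward()] trace produced with the same parameters.
#' @param params The parameters used for the forward pass.
#' @param arch The architecture.
#' @param targets One-hot matrix `[batch, 2]` (or a factor/character vector
#'   of class labels).
#' @return A gradient set mirroring the shapes of `params`.
#' @export
cnn_backward <- function(trace, params, arch, targets) {
  Y <- trace$probs
  R <- as_one_hot(targets, nrow(Y))
  B <- nrow(Y)
  if (arch$loss == "sse") {
    G <- 2 * (Y - R)
    s <- rowSums(G * Y)
    dz2 <- Y * (G - s) / B          # softmax Jacobian applied to dE/dY
  } else {
    dz2 <- (Y - R) / B
  }
  dW2 <- t(trace$y1d) %*% dz2
  db2 <- colSums(dz2)
  dy1d <- dz2 %*% t(params$dense[[2]]$W)
  dy1 <- if (is.null(trace$mask)) dy1d else dy1d * trace$mask
  dz1 <- dy1 * (1 - trace$y1^2)
  dW1 <- t(trace$flat) %*% dz1
  db1 <- colSums(dz1)
  delta <- array(dz1 %*% t(params$dense[[1]]$W), trace$conv_out_dims)

  conv_grads <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    rec <- trace$convs[[l]]
    if (!is.null(rec$pool)) delta <- pool_backward_batch(delta, rec$pool)
    delta_net <- delta * (rec$net > 0)           # ReLU derivative
    cb <- conv_backward_batch(delta_net, rec$x_in, params$conv[[l]]$W)
    conv_grads[[l]] <- list(W = cb$dW, b = cb$db)
    delta <- cb$din
  }
  structure(list(conv = conv_grads,
                 dense = list(list(W = dW1, b = db1),
                              list(W = dW2, b = db2))),
            class = "cnn_gradients")
}

as_one_hot <- function(targets, n) {
  if (is.matrix(targets)) return(targets)
  lab <- factor(targets, levels = mi_classes())
  R <- matrix(0, n, 2)
  R[cbind(seq_len(n), as.integer(lab))] <- 1
  R
}

#' Backpropagate deltas through a pooling layer
#'
#' Max pooling routes each incoming delta to the recorded argmax position of
#' its window (ties were broken toward the lowest index in the forward
#' pass), zeros elsewhere; average pooling divides each delta equally over
#' its window. The summed delta is conserved in both modes.
#'
#' @param delta_next Delta array shaped like the pooling output (a plain
#'   vector is treated as a single feature map).
#' @param mode `"max"` or `"average"`; must match the forward pass.
#' @param pool_trace The `trace` element returned by [pool_forward()].
#' @return Delta shaped like the pooling input.
#' @export
pool_backward <- function(delta_next, mode, pool_trace) {
  if (!identical(mode, pool_trace$mode))
    mi_input_error("mode does not match the recorded forward pass")
  vec <- is.null(dim(delta_next))
  if (vec) delta_next <- array(delta_next, c(1, 1, length(delta_next)))
  if (dim(delta_next)[3] != pool_trace$n_windows)
    mi_shape_error("delta length does not match the number of pool windows")
  din <- pool_backward_batch(delta_next, pool_trace)
  if (vec) as.numeric(din) else din
}

#' Forward pooling pass
#'
#' Non-overlapping pooling with window `width` (stride = width); a trailing
#' remainder shorter than the window is dropped.
#'
#' @param x Numeric vector (one feature map) or `[batch, depth, length]`
#'   array.
#' @param width Window width.
#' @param mode `"max"` or `"average"`.
#' @return List with `out` (pooled values, same rank as `x`) and `trace`
#'   (consumed by [pool_backward()]).
#' @export
pool_forward <- function(x, width, mode = c("max", "average")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  if (vec) x <- array(x, c(1, 1, length(x)))
  pf <- pool_forward_batch(x, width, mode)
  if (vec) pf$out <- as.numeric(pf$out)
  pf
}

#' One gradient-descent update
#'
#' `w <- w - eta * dE/dw` for every weight and bias.
#'
#' @param params A `cnn_parameters` object.
#' @param grads A matching gradient set from [cnn_backward()].
#' @param eta Positive learning rate.
#' @return Updated `cnn_parameters`.
#' @export
sgd_step <- function(params, grads, eta) {
  if (eta <= 0) mi_input_error("learning rate must be positive")
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$W <- params$conv[[l]]$W - eta * grads$conv[[l]]$W
    params$conv[[l]]$b <- params$conv[[l]]$b - eta * grads$conv[[l]]$b
  }
  for (l in seq_along(params$dense)) {
    params$dense[[l]]$W <- params$dense[[l]]$W - eta * grads$dense[[l]]$W
    params$dense[[l]]$b <- params$dense[[l]]$b - eta * grads$dense[[l]]$b
  }
  params
}

#' Classify feature vectors with a trained network
#'
#' Deterministic forward pass (no dropout); the label is the argmax
#' probability, ties broken toward the first class (`"left"`).
#'
#' @param params Trained `cnn_parameters`.
#' @param arch The architecture.
#' @param features Numeric vector of length `N`, or a matrix of rows.
#' @return List with `label` (factor) and `probabilities` (matrix
#'   `[n, 2]`, columns `left`, `right`).
#' @export
predict_cnn <- function(params, arch, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != arch$input_length)
    mi_shape_error("feature length does not match the architecture input")
  probs <- cnn_forward(params, arch, features)$probs
  colnames(probs) <- mi_classes()
  idx <- max.col(probs, ties.method = "first")
  list(label = factor(mi_classes()[idx], levels = mi_classes()),
       probabilities = probs)
}

# Flatten all parameters into one vector and back (finite-difference
# checks and serialization).
flatten_params <- function(params) {
  unlist(lapply(c(params$conv, params$dense),
                function(l) c(as.numeric(l$W), l$b)))
}

unflatten_params <- function(template, theta) {
  pos <- 0L
  take <- function(n) {
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  for (l in seq_along(template$conv)) {
    template$conv[[l]]$W <- array(take(length(template$conv[[l]]$W)),
                                  dim(template$conv[[l]]$W))
    template$conv[[l]]$b <- take(length(template$conv[[l]]$b))
  }
  for (l in seq_along(template$dense)) {
    template$dense[[l]]$W <- matrix(take(length(template$dense[[l]]$W)),
                                    nrow(template$dense[[l]]$W))
    template$dense[[l]]$b <- take(length(template$dense[[l]]$b))
  }
  template
}
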