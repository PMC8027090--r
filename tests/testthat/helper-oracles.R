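# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# Build an mi_trial directly from a channel x sample matrix.
make_trial <- function(samples, label = "left", fs = 100,
                       onset = 0, duration = ncol(samples) / fs) {
  structure(list(samples = samples, channel_names = c("C3", "C4"),
                 label = label, sampling_rate_hz = fs,
                 imagery_onset_s = onset, imagery_duration_s = duration),
            class = "mi_trial")
}

make_trialset <- function(trials, labels) {
  micnn:::new_trialset(trials, labels, NULL)
}

# Literal windowed-DFT summation for one STFT frame (frequency bin f).
naive_stft_frame <- function(padded_frame, f) {
  N <- length(padded_frame)
  n <- seq_len(N) - 1
  Mod(sum(padded_frame * exp(-2i * pi * f * n / N)))
}

# Literal triple-sum convolution (depth x kernel-row x kernel-col collapsed
# to 1-D) with ReLU, independent of the package's matrix formulation.
naive_conv <- function(input, kernels, bias, relu = TRUE) {
  D <- nrow(input); L <- ncol(input)
  K <- dim(kernels)[1]; Fk <- dim(kernels)[3]
  Lo <- L - Fk + 1
  out <- matrix(0, K, Lo)
  for (k in seq_len(K))
    for (j in seq_len(Lo)) {
      s <- bias[k]
      for (d in seq_len(D))
        for (m in seq_len(Fk))
          s <- s + kernels[k, d, m] * input[d, j + m - 1]
      out[k, j] <- if (relu) max(s, 0) else s
    }
  out
}

# Central finite-difference gradient check on a single sample; returns the
# worst relative error over all parameters.
grad_check_rel <- function(arch, seed, h = 1e-5) {
  params <- init_parameters(arch, seed)
  x <- matrix(stats::rnorm(arch$input_length), 1)
  R <- matrix(c(1, 0), 1)
  loss_of <- function(p) {
    probs <- cnn_forward(p, arch, x)$probs[1, ]
    if (arch$loss == "sse") sum((probs - c(1, 0))^2)
    else -sum(c(1, 0) * log(probs))
  }
  analytic <- micnn:::flatten_params(
    cnn_backward(cnn_forward(params, arch, x), params, arch, R))
  theta <- micnn:::flatten_params(params)
  numeric_grad <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (loss_of(micnn:::unflatten_params(params, tp)) -
       loss_of(micnn:::unflatten_params(params, tm))) / (2 * h)
  }, numeric(1))
  max(abs(analytic - numeric_grad) / pmax(abs(numeric_grad), 1e-3))
}

# Small linearly separable feature set in R^4.
toy_features <- function(n_per_class = 16, seed = 3, spread = 0.2) {
  set.seed(seed)
  centers <- rbind(left = c(1, 1, -1, -1), right = c(-1, -1, 1, 1))
  x <- rbind(
    matrix(stats::rnorm(4 * n_per_class, sd = spread), ncol = 4,
           byrow = TRUE) + matrix(centers[1, ], n_per_class, 4, byrow = TRUE),
    matrix(stats::rnorm(4 * n_per_class, sd = spread), ncol = 4,
           byrow = TRUE) + matrix(centers[2, ], n_per_class, 4, byrow = TRUE))
  list(x = x, y = rep(c("left", "right"), each = n_per_class))
}
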