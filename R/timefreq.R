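#' Short-time Fourier transform magnitude spectrogram
#'
#' Splits the signal into Hamming-windowed frames and returns the magnitude
#' of the discrete Fourier transform of each frame. Frames are centered at
#' samples `0, hop, 2*hop, ...` (zero-padded where the window extends past
#' the signal), and each windowed frame is zero-padded to `transform_length`
#' before the DFT. With the defaults, a 3.5 s signal at 100 Hz yields a
#' 33 (frequency) x 35 (time) matrix.
#'
#' @param signal Numeric vector.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_length_s Analysis window length in seconds (default 0.5 s).
#' @param hop_samples Frame advance in samples (default 10).
#' @param transform_length DFT length; must be >= window length in samples.
#' @param method `"fft"` (default) or `"direct"` (literal windowed DFT
#'   summation; identical result, used for verification).
#' @return Object of class `mi_spectrogram`: `magnitudes`
#'   (`transform_length/2 + 1` x n_frames), `freqs_hz`, `times_s`,
#'   `window` (the Hamming window vector), `window_length_s`, `hop_samples`,
#'   `transform_length`.
#' @export
stft <- function(signal, sampling_rate_hz, window_length_s = 0.5,
                 hop_samples = 10L, transform_length = 64L,
                 method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- length(signal)
  wlen <- round(window_length_s * sampling_rate_hz)
  if (wlen < 1 || hop_samples < 1)
    mi_input_error("window length and hop must be positive")
  if (wlen > transform_length)
    mi_input_error("window length in samples must not exceed transform_length")
  if (n < wlen)
    mi_input_error("signal is shorter than one analysis window")

  w <- signal::hamming(wlen)
  centers <- seq(0L, n - 1L, by = hop_samples)
  half <- floor(wlen / 2)
  nb <- transform_length %/% 2 + 1

  mags <- matrix(0, nb, length(centers))
  for (k in seq_along(centers)) {
    idx <- (centers[k] - half):(centers[k] - half + wlen - 1)
    frame <- numeric(wlen)
    inside <- idx >= 0 & idx <= n - 1
    frame[inside] <- signal[idx[inside] + 1]
    frame <- frame * w
    padded <- c(frame, numeric(transform_length - wlen))
    spec <- if (method == "fft") {
      stats::fft(padded)
    } else {
      vapply(seq_len(transform_length) - 1, function(f)
        sum(padded * exp(-2i * pi * f * (seq_len(transform_length) - 1) /
                           transform_length)),
        complex(1))
    }
    mags[, k] <- Mod(spec[seq_len(nb)])
  }
  structure(list(magnitudes = mags,
                 freqs_hz = (seq_len(nb) - 1) * sampling_rate_hz / transform_length,
                 times_s = centers / sampling_rate_hz,
                 window = as.numeric(w),
                 window_length_s = window_length_s,
                 hop_samples = as.integer(hop_samples),
                 transform_length = as.integer(transform_length)),
            class = "mi_spectrogram")
}

#' Stacked two-channel STFT feature tensor for a trial
#'
#' Applies [stft()] to the imagery-window segment of each channel and stacks
#' the magnitude matrices into a `frequency x time x channel` array. Under
#' the default parameters a 3.5 s imagery window at 100 Hz gives a
#' `33 x 35 x 2` tensor.
#'
#' @param trial An `mi_trial`.
#' @param imagery_window `(start_s, duration_s)` relative to trial start;
#'   defaults to the trial's own imagery window.
#' @param ... Passed to [stft()].
#' @return Object of class `mi_feature_tensor`: `values` (3-d array),
#'   `freqs_hz`, `times_s`, `channel_names`, `kind = "stft"`.
#' @export
stft_feature_tensor <- function(trial,
                                imagery_window = c(trial$imagery_onset_s,
                                                   trial$imagery_duration_s),
                                ...) {
  if (nrow(trial$samples) != 2) mi_input_error("trial must have 2 channels")
  idx <- sample_window(imagery_window[1], imagery_window[2],
                       trial$sampling_rate_hz, ncol(trial$samples))
  specs <- lapply(1:2, function(ch)
    stft(trial$samples[ch, idx], trial$sampling_rate_hz, ...))
  values <- array(0, c(dim(specs[[1]]$magnitudes), 2),
                  dimnames = list(NULL, NULL, trial$channel_names))
  values[, , 1] <- specs[[1]]$magnitudes
  values[, , 2] <- specs[[2]]$magnitudes
  structure(list(values = values,
                 freqs_hz = specs[[1]]$freqs_hz,
                 times_s = specs[[1]]$times_s,
                 channel_names = trial$channel_names,
                 kind = "stft"),
            class = "mi_feature_tensor")
}

#' Morlet-type mother wavelet
#'
#' The real mother wavelet `psi(x) = exp(-x^2) * cos(pi * sqrt(2/ln 2) * x)`:
#' a Gaussian-enveloped cosine whose spectrum is centered near
#' `pi * sqrt(2/ln 2) ~= 5.34` rad/s. Even in `x` and decaying as
#' `exp(-x^2)`.
#'
#' @param x Numeric vector.
#' @return `psi(x)`.
#' @export
morlet_mother <- function(x) exp(-x^2) * cos(pi * sqrt(2 / log(2)) * x)

#' Time and frequency moments of a mother wavelet
#'
#' Computes the center time, RMS time span, center frequency and RMS
#' bandwidth of a wavelet by discrete quadrature of the normalized second
#' moments of `|psi(t)|^2` and `|Psi(omega)|^2`, where `Psi` is the Fourier
#' transform of `psi` evaluated by trapezoidal quadrature. Because a real
#' wavelet has an even power spectrum, the frequency-domain moments are taken
#' over `omega in [0, Inf)` (over the full line the first moment of an even
#' spectrum is identically zero).
#'
#' @param psi A vectorized mother-wavelet function.
#' @param t_range Length-2 time-grid range; `|psi|` must be < 1e-8 at the
#'   boundaries or a precision error is raised.
#' @param dt Time-grid step.
#' @param omega_max,domega Frequency grid extent (rad/s) and step.
#' @return Object of class `wavelet_moments`: `center_time`, `time_span`,
#'   `center_frequency` (rad/s), `bandwidth` (rad/s), plus the evaluated
#'   spectrum (`omega`, `spectrum`).
#' @export
wavelet_moments <- function(psi = morlet_mother, t_range = c(-8, 8),
                            dt = 0.001, omega_max = 40, domega = 0.01) {
  if (max(abs(psi(t_range))) >= 1e-8)
    mi_precision_error("time grid too narrow: |psi| at the boundary >= 1e-8")
  t <- seq(t_range[1], t_range[2], by = dt)
  p <- psi(t)
  p2 <- p^2
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
  norm_t <- trapz(t, p2)
  t0 <- trapz(t, t * p2) / norm_t
  dt_psi <- sqrt(trapz(t, (t - t0)^2 * p2) / norm_t)

  omega <- seq(0, omega_max, by = domega)
  Psi <- vapply(omega, function(w) trapz(t, p * cos(w * t)) -
                  1i * trapz(t, p * sin(w * t)), complex(1))
  S <- Mod(Psi)^2
  norm_w <- trapz(omega, S)
  w0 <- trapz(omega, omega * S) / norm_w
  dw_psi <- sqrt(trapz(omega, (omega - w0)^2 * S) / norm_w)

  structure(list(center_time = t0, time_span = dt_psi,
                 center_frequency = w0, bandwidth = dw_psi,
                 omega = omega, spectrum = S),
            class = "wavelet_moments")
}

# Cached center frequency of the default mother wavelet (rad/s); analytic
# value pi*sqrt(2/ln 2) is the cosine frequency, to which the one-sided
# spectral mean is very close.
morlet_center_frequency <- function() pi * sqrt(2 / log(2))

#' Continuous wavelet transform (real Morlet-type scalogram)
#'
#' Computes `W(a, b) = sum_t x(t) * (1/sqrt(a)) * psi((t - b)/a)` over the
#' sample grid (`t`, `b` in seconds at the sampling resolution), for every
#' scale `a` and one shift per sample. The `"fft"` method evaluates the same
#' discrete sum by frequency-domain convolution and agrees with the literal
#' `"direct"` summation to floating-point precision.
#'
#' @param signal Numeric vector (nonempty).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param scales Strictly positive, strictly increasing vector of scales
#'   (seconds).
#' @param psi Mother wavelet function.
#' @param method `"fft"` (default) or `"direct"`.
#' @return Object of class `mi_scalogram`: `coefficients`
#'   (`n_scales x n_samples`), `scales`, `pseudo_freqs_hz`
#'   (`center_frequency / (2 pi a)`), `times_s`.
#' @export
cwt <- function(signal, sampling_rate_hz, scales, psi = morlet_mother,
                method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- length(signal)
  if (n < 1) mi_input_error("signal must be nonempty")
  if (any(scales <= 0)) mi_input_error("scales must be strictly positive")
  if (length(scales) > 1 && any(diff(scales) <= 0))
    mi_input_error("scales must be strictly increasing")

  fs <- sampling_rate_hz
  coef <- matrix(0, length(scales), n)
  tau <- (-(n - 1)):(n - 1) / fs       # lag grid in seconds
  for (s in seq_along(scales)) {
    a <- scales[s]
    g <- (1 / sqrt(a)) * psi(tau / a)  # g[j] = psi_a(tau_j), j = -(n-1)..(n-1)
    if (method == "direct") {
      t_s <- (seq_len(n) - 1) / fs
      for (b in seq_len(n))
        coef[s, b] <- sum(signal * (1 / sqrt(a)) * psi((t_s - t_s[b]) / a))
    } else {
      # W[b] = sum_m x[m] g[m - b] : correlation via zero-padded FFT
      L <- n + 2 * n - 2
      X <- stats::fft(c(signal, numeric(L - n)))
      G <- stats::fft(c(g, numeric(L - length(g))))
      full <- Re(stats::fft(X * Conj(G) * exp(-2i * pi * (n - 1) *
                                                (seq_len(L) - 1) / L),
                            inverse = TRUE)) / L
      coef[s, ] <- full[seq_len(n)]
    }
  }
  structure(list(coefficients = coef,
                 scales = as.numeric(scales),
                 pseudo_freqs_hz = morlet_center_frequency() / (2 * pi * scales),
                 times_s = (seq_len(n) - 1) / fs),
            class = "mi_scalogram")
}

#' Stacked two-channel scalogram feature tensor
#'
#' Applies [cwt()] to each full-length channel with `n_scales` log-spaced
#' scales whose pseudo-frequencies cover `freq_range_hz` (default 4-40 Hz),
#' stacking the coefficient matrices into a
#' `n_scales x n_samples x 2` array.
#'
#' @param trial An `mi_trial`.
#' @param n_scales Number of scales (default 35).
#' @param freq_range_hz Pseudo-frequency coverage `(low, high)` in Hz.
#' @return An `mi_feature_tensor` with `kind = "cwt"`.
#' @export
cwt_feature_tensor <- function(trial, n_scales = 35L,
                               freq_range_hz = c(4, 40)) {
  if (nrow(trial$samples) != 2) mi_input_error("trial must have 2 channels")
  if (n_scales < 1) mi_input_error("n_scales must be >= 1")
  w0 <- morlet_center_frequency()
  # increasing scales = decreasing pseudo-frequency (high freq first scale)
  scales <- exp(seq(log(w0 / (2 * pi * freq_range_hz[2])),
                    log(w0 / (2 * pi * freq_range_hz[1])),
                    length.out = n_scales))
  scs <- lapply(1:2, function(ch)
    cwt(trial$samples[ch, ], trial$sampling_rate_hz, scales))
  values <- array(0, c(n_scales, ncol(trial$samples), 2),
                  dimnames = list(NULL, NULL, trial$channel_names))
  values[, , 1] <- scs[[1]]$coefficients
  values[, , 2] <- scs[[2]]$coefficients
  structure(list(values = values,
                 scales = scales,
                 pseudo_freqs_hz = scs[[1]]$pseudo_freqs_hz,
                 times_s = scs[[1]]$times_s,
                 channel_names = trial$channel_names,
                 kind = "cwt"),
            class = "mi_feature_tensor")
}

#' Flatten a feature tensor to a single CNN input row
#'
#' Column-major flattening of the `frequency x time x channel` array into a
#' numeric vector (the 33 x 35 x 2 STFT tensor becomes length 2310).
#'
#' @param tensor An `mi_feature_tensor`.
#' @return Numeric vector.
#' @export
flatten_feature_tensor <- function(tensor) as.numeric(tensor$values)
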