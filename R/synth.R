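#' Configuration for the synthetic motor-imagery trial generator
#'
#' Describes the simulated recording protocol: a 7 s trial sampled at 100 Hz
#' with a 3.5 s imagery window starting at 1.5 s, and the two-channel (C3,
#' C4) signal model. Each channel is the sum of 1/f-shaped broadband
#' background noise, a mu-band (8-12 Hz) oscillation and a beta-band
#' (12-25 Hz) oscillation. Inside the imagery window the mu amplitude on the
#' channel contralateral to the imagined hand is reduced by `erd_depth`
#' (event-related desynchronization) and the beta amplitude on the
#' ipsilateral channel is increased by `ers_gain` (event-related
#' synchronization). C3 (left hemisphere) is contralateral to right-hand
#' imagery, C4 to left-hand imagery.
#'
#' Amplitudes are RMS values in arbitrary microvolt-scaled units.
#' `oscillation_mode = "narrowband"` synthesizes each rhythm as 4th-order
#' band-pass filtered Gaussian noise (realistic variance structure for CSP);
#' `"sinusoid"` uses a fixed-frequency random-phase cosine at the band
#' center, which makes band-power calculations exactly predictable and is
#' intended for verification.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param trial_duration_s Trial length in seconds.
#' @param imagery_onset_s Start of the imagery window, seconds from trial start.
#' @param imagery_duration_s Length of the imagery window in seconds.
#' @param mu_band_hz,beta_band_hz Length-2 `(low, high)` band edges in Hz.
#' @param mu_base_amplitude,beta_base_amplitude Baseline RMS amplitude of each
#'   rhythm outside the imagery window.
#' @param erd_depth Fractional mu-amplitude reduction in `[0, 1]` on the
#'   contralateral channel during imagery.
#' @param ers_gain Fractional beta-amplitude increase (nonnegative) on the
#'   ipsilateral channel during imagery.
#' @param noise_amplitude RMS of the 1/f background noise.
#' @param ramp_s Raised-cosine amplitude ramp at the imagery-window edges.
#' @param oscillation_mode `"narrowband"` (default) or `"sinusoid"`.
#' @param seed Integer seed making [generate_dataset()] fully reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate_hz = 100,
                             trial_duration_s = 7,
                             imagery_onset_s = 1.5,
                             imagery_duration_s = 3.5,
                             mu_band_hz = c(8, 12),
                             beta_band_hz = c(12, 25),
                             mu_base_amplitude = 1.5,
                             beta_base_amplitude = 1.0,
                             erd_depth = 0.5,
                             ers_gain = 0.5,
                             noise_amplitude = 1.0,
                             ramp_s = 0.1,
                             oscillation_mode = c("narrowband", "sinusoid"),
                             seed = 1L) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    trial_duration_s = trial_duration_s,
    imagery_onset_s = imagery_onset_s,
    imagery_duration_s = imagery_duration_s,
    mu_band_hz = as.numeric(mu_band_hz),
    beta_band_hz = as.numeric(beta_band_hz),
    mu_base_amplitude = mu_base_amplitude,
    beta_base_amplitude = beta_base_amplitude,
    erd_depth = erd_depth,
    ers_gain = ers_gain,
    noise_amplitude = noise_amplitude,
    ramp_s = ramp_s,
    oscillation_mode = match.arg(oscillation_mode),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  ok_band <- function(b) length(b) == 2 && b[1] > 0 && b[1] < b[2] &&
    b[2] < cfg$sampling_rate_hz / 2
  if (cfg$sampling_rate_hz <= 0 || cfg$trial_duration_s <= 0)
    mi_config_error("sampling rate and trial duration must be positive")
  if (cfg$imagery_onset_s < 0 || cfg$imagery_duration_s <= 0)
    mi_config_error("imagery window must have nonnegative onset and positive duration")
  if (cfg$imagery_onset_s + cfg$imagery_duration_s > cfg$trial_duration_s + 1e-12)
    mi_config_error("imagery window must fit inside the trial")
  if (!ok_band(cfg$mu_band_hz) || !ok_band(cfg$beta_band_hz))
    mi_config_error("band edges must satisfy 0 < low < high < Nyquist")
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    mi_config_error("erd_depth must lie in [0, 1]")
  if (cfg$ers_gain < 0 || cfg$noise_amplitude < 0 ||
      cfg$mu_base_amplitude < 0 || cfg$beta_base_amplitude < 0)
    mi_config_error("amplitudes and ers_gain must be nonnegative")
  invisible(cfg)
}

n_samples_of <- function(cfg) round(cfg$trial_duration_s * cfg$sampling_rate_hz)

# 1/f-shaped Gaussian noise, unit RMS. Spectral shaping is applied in the
# frequency domain with a 1 Hz floor so the DC-adjacent bins do not dominate.
one_over_f_noise <- function(n, fs) {
  x <- stats::fft(stats::rnorm(n))
  freq <- (seq_len(n) - 1) * fs / n
  f2 <- pmin(freq, fs - freq)          # two-sided frequency magnitude
  amp <- 1 / sqrt(pmax(f2, 1))
  amp[1] <- 0                          # remove DC
  y <- Re(stats::fft(x * amp, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Band-limited Gaussian process, unit RMS: white noise through a 4th-order
# Butterworth band-pass applied forward-backward (zero phase). Generation
# padding absorbs the filter transient.
narrowband_oscillation <- function(n, fs, band) {
  pad <- max(200L, round(2 * fs))
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  y <- y[(pad + 1):(pad + n)]
  y / sqrt(mean(y^2))
}

sinusoid_oscillation <- function(n, fs, band) {
  f0 <- mean(band)
  phase <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  sqrt(2) * cos(2 * pi * f0 * t + phase)   # unit RMS
}

# Amplitude envelope: 1 outside the imagery window, `factor` inside, with
# raised-cosine ramps of length ramp_s just inside each window edge.
imagery_envelope <- function(n, fs, onset, duration, factor, ramp_s) {
  t <- (seq_len(n) - 1) / fs
  s <- numeric(n)
  in_win <- t >= onset & t < onset + duration
  s[in_win] <- 1
  if (ramp_s > 0) {
    up <- in_win & t < onset + ramp_s
    s[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp_s))
    down <- in_win & t >= onset + duration - ramp_s
    s[down] <- 0.5 * (1 - cos(pi * (onset + duration - t[down]) / ramp_s))
  }
  1 + (factor - 1) * s
}

#' Generate one synthetic motor-imagery trial
#'
#' Draws a single two-channel trial from the signal model described in
#' [generator_config()], using the current state of R's random number
#' generator (seed the stream yourself, or use [generate_dataset()] which
#' seeds from `config$seed`).
#'
#' @param config A [generator_config()].
#' @param label `"left"` or `"right"` hand imagery.
#' @return An object of class `mi_trial`: list with `samples` (2 x n matrix,
#'   rows C3 then C4), `channel_names`, `label`, `sampling_rate_hz`,
#'   `imagery_onset_s`, `imagery_duration_s`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- generate_trial(generator_config(), "left")
#' dim(tr$samples)   # 2 x 700
generate_trial <- function(config, label) {
  validate_generator_config(config)
  label <- as_mi_label(label)
  n <- n_samples_of(config)
  fs <- config$sampling_rate_hz

  # contralateral mapping: C3 <-> right hand, C4 <-> left hand
  contra <- if (label == "right") "C3" else "C4"
  ipsi   <- if (label == "right") "C4" else "C3"

  osc <- switch(config$oscillation_mode,
                narrowband = narrowband_oscillation,
                sinusoid = sinusoid_oscillation)

  make_channel <- function(name) {
    mu_factor <- if (name == contra) 1 - config$erd_depth else 1
    beta_factor <- if (name == ipsi) 1 + config$ers_gain else 1
    env_mu <- imagery_envelope(n, fs, config$imagery_onset_s,
                               config$imagery_duration_s, mu_factor,
                               config$ramp_s)
    env_beta <- imagery_envelope(n, fs, config$imagery_onset_s,
                                 config$imagery_duration_s, beta_factor,
                                 config$ramp_s)
    noise <- if (config$noise_amplitude > 0)
      config$noise_amplitude * one_over_f_noise(n, fs) else numeric(n)
    config$mu_base_amplitude * env_mu * osc(n, fs, config$mu_band_hz) +
      config$beta_base_amplitude * env_beta * osc(n, fs, config$beta_band_hz) +
      noise
  }

  samples <- rbind(C3 = make_channel("C3"), C4 = make_channel("C4"))
  structure(list(samples = samples,
                 channel_names = c("C3", "C4"),
                 label = label,
                 sampling_rate_hz = fs,
                 imagery_onset_s = config$imagery_onset_s,
                 imagery_duration_s = config$imagery_duration_s),
            class = "mi_trial")
}

#' Generate a balanced, reproducible set of synthetic trials
#'
#' @param config A [generator_config()]; `config$seed` determines the whole
#'   dataset (same config twice gives bit-identical samples).
#' @param n_per_class Number of trials per class (left, right).
#' @return An object of class `mi_trialset`: list with `trials` (list of
#'   [generate_trial()] results), `labels` (factor), `config`.
#' @export
generate_dataset <- function(config, n_per_class) {
  validate_generator_config(config)
  if (!is.numeric(n_per_class) || n_per_class < 1)
    mi_input_error("n_per_class must be a positive integer")
  n_per_class <- as.integer(n_per_class)
  labels <- rep(mi_classes(), each = n_per_class)
  set.seed(config$seed)
  trials <- lapply(labels, function(lb) generate_trial(config, lb))
  new_trialset(trials, labels, config)
}

new_trialset <- function(trials, labels, config) {
  labels <- factor(labels, levels = mi_classes())
  if (length(trials) != length(labels))
    mi_input_error("trials and labels must have equal length")
  structure(list(trials = trials, labels = labels, config = config),
            class = "mi_trialset")
}

#' @export
print.mi_trialset <- function(x, ...) {
  cat(sprintf("<mi_trialset> %d trials (%s), %d channels x %d samples @ %g Hz\n",
              length(x$trials),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              nrow(x$trials[[1]]$samples), ncol(x$trials[[1]]$samples),
              x$trials[[1]]$sampling_rate_hz))
  invisible(x)
}

#' @export
print.mi_trial <- function(x, ...) {
  cat(sprintf("<mi_trial> label=%s, %d x %d samples @ %g Hz\n", x$label,
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz))
  invisible(x)
}

#' Mean band power of a signal by periodogram integration
#'
#' Sums the one-sided periodogram over all frequency bins inside `band`.
#' For a sinusoid of amplitude A whose frequency falls on a bin, the result
#' is A^2/2; the quantity is linear in squared amplitude.
#'
#' @param signal Numeric vector.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param band Length-2 `(low, high)` in Hz, inside `(0, Nyquist)`.
#' @return Nonnegative scalar band power.
#' @export
band_power <- function(signal, sampling_rate_hz, band) {
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 ||
      band[2] > sampling_rate_hz / 2)
    mi_input_error("band must lie inside (0, Nyquist)")
  n <- length(signal)
  X <- stats::fft(signal)
  nb <- floor(n / 2) + 1
  freqs <- (seq_len(nb) - 1) * sampling_rate_hz / n
  p <- Mod(X[seq_len(nb)])^2 / n^2
  mult <- rep(2, nb)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nb] <- 1    # Nyquist bin is unpaired
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(p[sel] * mult[sel])
}

# Window of sample indices covering [start_s, start_s + duration_s)
sample_window <- function(start_s, duration_s, fs, n) {
  i0 <- round(start_s * fs) + 1
  i1 <- i0 + round(duration_s * fs) - 1
  if (i0 < 1 || i1 > n)
    mi_input_error("requested window lies outside the trial")
  i0:i1
}
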