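#' Band-pass filter a multichannel sample matrix
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase) to
#' each row of a `channels x samples` matrix.
#'
#' @param samples Numeric matrix, one channel per row.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param band `(low, high)` in Hz.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_samples <- function(samples, sampling_rate_hz, band) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= sampling_rate_hz / 2)
    mi_input_error("band must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(2, band / (sampling_rate_hz / 2), type = "pass")
  t(apply(samples, 1, function(x) signal::filtfilt(bf, x)))
}

#' Average trace-normalized class covariances in a frequency band
#'
#' Each trial is band-pass filtered, its spatial covariance `X X'` is
#' normalized to unit trace, and the normalized covariances are averaged
#' within each class. Trace normalization makes the result invariant to
#' per-trial amplitude scaling.
#'
#' @param trialset An `mi_trialset` with at least one trial per class.
#' @param band `(low, high)` in Hz.
#' @return Object of class `class_covariances`: `cov_per_class` (named list
#'   `left`, `right` of symmetric unit-trace matrices),
#'   `n_trials_per_class`, `band`.
#' @export
class_covariances <- function(trialset, band) {
  counts <- table(trialset$labels)
  if (any(counts < 1))
    mi_input_error("each class needs at least one trial")
  fs <- trialset$trials[[1]]$sampling_rate_hz
  covs <- lapply(trialset$trials, function(tr) {
    Xf <- bandpass_samples(tr$samples, fs, band)
    C <- Xf %*% t(Xf)
    C / sum(diag(C))
  })
  avg <- function(cls) {
    sel <- which(trialset$labels == cls)
    Reduce(`+`, covs[sel]) / length(sel)
  }
  structure(list(cov_per_class = list(left = avg("left"), right = avg("right")),
                 n_trials_per_class = as.integer(counts),
                 band = band),
            class = "class_covariances")
}

#' Fit common spatial pattern filters for one band
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` (class 1 =
#' left) by whitening the composite covariance and eigendecomposing the
#' whitened class-1 covariance. Returns the `m` filters with the largest and
#' the `m` with the smallest eigenvalues, scaled so that
#' `W (C1 + C2) W' = I`. Eigenvalues lie in (0, 1); the eigenvalue of the
#' same filter computed from class 2 is `1 - lambda` (complementarity).
#'
#' If the composite covariance is numerically singular, a ridge `1e-8 * I` is
#' added before whitening; if it is still not positive definite the function
#' fails with a numerical error.
#'
#' @param covs A [class_covariances()] object (or a list with
#'   `cov_per_class`).
#' @param m Number of filter pairs; `2 * m` must not exceed the channel count.
#' @return List with `filters` (`2m x n_ch`, rows are spatial filters, the
#'   first `m` maximize class-left variance), `eigenvalues` (the selected
#'   lambdas, descending), `all_eigenvalues`.
#' @export
fit_csp <- function(covs, m = 1L) {
  C1 <- covs$cov_per_class[[1]]
  C2 <- covs$cov_per_class[[2]]
  nch <- nrow(C1)
  if (2 * m > nch)
    mi_input_error("2*m must not exceed the number of channels")
  Cc <- C1 + C2
  eg <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    Cc <- Cc + diag(1e-8, nch)
    eg <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)
    if (min(eg$values) <= 0)
      mi_numeric_error(paste0(
        "composite covariance is singular even after ridge regularization ",
        "(1e-8); check for duplicated or zero-variance channels"))
  }
  P <- diag(1 / sqrt(eg$values), nch) %*% t(eg$vectors)  # whitening: P Cc P' = I
  S <- P %*% C1 %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)          # values descending
  W <- t(es$vectors) %*% P                               # rows: all filters
  sel <- c(seq_len(m), (nch - m + 1):nch)
  list(filters = W[sel, , drop = FALSE],
       eigenvalues = es$values[sel],
       all_eigenvalues = es$values)
}

#' Fit a two-band CSP model on a trial set
#'
#' Fits [fit_csp()] independently in each frequency band (defaults: mu
#' 8-12 Hz and beta 12-25 Hz) and bundles the filters into a model producing
#' length `4*m` feature vectors (`2m` log-variance features per band).
#'
#' @param trialset An `mi_trialset`.
#' @param bands Named list of `(low, high)` bands.
#' @param m Filter pairs per band.
#' @return Object of class `csp_model`: `bands`, `m`, `filters_per_band`,
#'   `eigenvalues_per_band`, `sampling_rate_hz`, `n_features`.
#' @export
fit_csp_model <- function(trialset,
                          bands = list(mu = c(8, 12), beta = c(12, 25)),
                          m = 1L) {
  fits <- lapply(bands, function(b) fit_csp(class_covariances(trialset, b), m))
  structure(list(bands = bands,
                 m = as.integer(m),
                 filters_per_band = lapply(fits, `[[`, "filters"),
                 eigenvalues_per_band = lapply(fits, `[[`, "eigenvalues"),
                 sampling_rate_hz = trialset$trials[[1]]$sampling_rate_hz,
                 n_features = as.integer(2 * m * length(bands))),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d bands (%s), m=%d, %d features\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              x$m, x$n_features))
  invisible(x)
}

#' CSP log-variance features of one trial
#'
#' Per band: band-pass filter the trial, project it through the band's `2m`
#' spatial filters, and compute the log of each projection's variance
#' normalized by the sum of the `2m` variances. Band blocks are concatenated
#' into a vector of length `4*m` (two bands). A floor of `1e-12` inside the
#' log guards zero-variance projections.
#'
#' @param trial An `mi_trial` with a channel count matching the model.
#' @param model A [fit_csp_model()] result.
#' @return Numeric vector of length `model$n_features`.
#' @export
csp_features <- function(trial, model) {
  if (nrow(trial$samples) != ncol(model$filters_per_band[[1]]))
    mi_shape_error("trial channel count does not match the CSP model")
  unlist(lapply(seq_along(model$bands), function(i) {
    Xf <- bandpass_samples(trial$samples, model$sampling_rate_hz,
                           model$bands[[i]])
    Y <- model$filters_per_band[[i]] %*% Xf
    v <- apply(Y, 1, stats::var)
    log(pmax(v / sum(v), 1e-12))
  }), use.names = FALSE)
}

#' CSP feature matrix for a whole trial set
#'
#' @param trialset An `mi_trialset`.
#' @param model A [fit_csp_model()] result.
#' @return Numeric matrix `n_trials x n_features`.
#' @export
csp_feature_matrix <- function(trialset, model) {
  t(vapply(trialset$trials, csp_features, numeric(model$n_features),
           model = model))
}
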