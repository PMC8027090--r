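test_that("class covariances are symmetric, unit-trace and scale-invariant", {
  set.seed(20)
  trials <- lapply(1:20, function(i) make_trial(matrix(rnorm(2 * 400), 2)))
  ts <- make_trialset(trials, rep(c("left", "right"), 10))
  cc <- class_covariances(ts, c(8, 12))
  for (C in cc$cov_per_class) {
    expect_equal(sum(diag(C)), 1, tolerance = 1e-12)
    expect_lt(max(abs(C - t(C))), 1e-12)
    # independent equal-variance channels: close to diag(0.5, 0.5)
    expect_equal(diag(C), c(0.5, 0.5), tolerance = 0.1)
    expect_lt(abs(C[1, 2]), 0.1)
  }
  # scaling all samples leaves the normalized covariances unchanged
  ts10 <- make_trialset(lapply(trials, function(tr) {
    tr$samples <- tr$samples * 10
    tr
  }), ts$labels)
  cc10 <- class_covariances(ts10, c(8, 12))
  expect_equal(cc$cov_per_class, cc10$cov_per_class, tolerance = 1e-12)

  # a duplicated single trial gives exactly that trial's covariance
  one <- make_trialset(trials[c(1, 1)], c("left", "right"))
  Xf <- bandpass_samples(trials[[1]]$samples, 100, c(8, 12))
  C <- Xf %*% t(Xf)
  expect_equal(class_covariances(one, c(8, 12))$cov_per_class$left,
               C / sum(diag(C)), tolerance = 1e-12)
  expect_error(class_covariances(make_trialset(trials[1:2], c("left", "left")),
                                 c(8, 12)),
               class = "micnn_input_error")
})

test_that("fit_csp solves the 2x2 generalized eigenproblem in closed form", {
  covs <- list(cov_per_class = list(left = diag(c(4, 1)) / 5,
                                    right = diag(c(1, 4)) / 5))
  fit <- fit_csp(covs, m = 1)
  expect_equal(fit$eigenvalues, c(0.8, 0.2), tolerance = 1e-10)
  # filters aligned with the coordinate axes
  expect_equal(abs(fit$filters) / max(abs(fit$filters)),
               matrix(c(1, 0, 0, 1), 2, byrow = TRUE), tolerance = 1e-10)
  # identical class covariances: all eigenvalues 1/2
  same <- list(cov_per_class = list(left = diag(2) / 2, right = diag(2) / 2))
  expect_equal(fit_csp(same, 1)$eigenvalues, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(fit_csp(covs, m = 2), class = "micnn_input_error")
})

test_that("filters whiten the composite covariance and eigenvalues are complementary", {
  set.seed(21)
  ts <- generate_dataset(generator_config(seed = 23L), 20)
  for (band in list(c(8, 12), c(12, 25))) {
    cc <- class_covariances(ts, band)
    fit <- fit_csp(cc, m = 1)
    Cc <- cc$cov_per_class$left + cc$cov_per_class$right
    expect_lt(max(abs(fit$filters %*% Cc %*% t(fit$filters) - diag(2))), 1e-8)
    # swapping the class roles gives 1 - lambda for the same filters
    swapped <- list(cov_per_class = rev(cc$cov_per_class))
    expect_equal(fit$all_eigenvalues + rev(fit_csp(swapped, 1)$all_eigenvalues),
                 rep(1, 2), tolerance = 1e-8)
  }
})

test_that("log-variance features have length 4m and match hand computations", {
  set.seed(22)
  ts <- generate_dataset(generator_config(seed = 24L), 10)
  model <- fit_csp_model(ts)
  expect_identical(model$n_features, 4L)
  f <- csp_features(ts$trials[[1]], model)
  expect_length(f, 4)
  expect_true(all(is.finite(f)))

  # axis-aligned identity filters and 2:1 channel amplitudes -> normalized
  # band variances (0.8, 0.2) in both bands
  t <- (0:499) / 100
  base <- cos(2 * pi * 10 * t) + cos(2 * pi * 18 * t)
  toy <- make_trial(rbind(2 * base, base))
  toy_model <- structure(list(
    bands = list(mu = c(8, 12), beta = c(12, 25)), m = 1L,
    filters_per_band = list(mu = diag(2), beta = diag(2)),
    sampling_rate_hz = 100, n_features = 4L), class = "csp_model")
  expect_equal(csp_features(toy, toy_model),
               rep(c(log(0.8), log(0.2)), 2), tolerance = 1e-6)

  # equal variance under both filters -> log(1/2) everywhere
  eq <- make_trial(rbind(base, base))
  expect_equal(csp_features(eq, toy_model), rep(log(0.5), 4),
               tolerance = 1e-9)

  # zero-variance projection is guarded by the log floor, not -Inf
  rot <- matrix(c(1, 1, 1, -1) / sqrt(2), 2, byrow = TRUE)
  eq_model <- toy_model
  eq_model$filters_per_band <- list(mu = rot, beta = rot)
  expect_true(all(is.finite(csp_features(eq, eq_model))))
})

test_that("channel permutation permutes filters but leaves features unchanged", {
  ts <- generate_dataset(generator_config(seed = 25L), 15)
  swapped <- make_trialset(lapply(ts$trials, function(tr) {
    tr$samples <- tr$samples[2:1, ]
    rownames(tr$samples) <- c("C3", "C4")
    tr
  }), ts$labels)
  m1 <- fit_csp_model(ts)
  m2 <- fit_csp_model(swapped)
  for (b in c("mu", "beta")) {
    expect_equal(abs(m2$filters_per_band[[b]]),
                 abs(m1$filters_per_band[[b]][, 2:1]), tolerance = 1e-8)
  }
  f1 <- csp_features(ts$trials[[3]], m1)
  f2 <- csp_features(swapped$trials[[3]], m2)
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("the first mu-band feature separates the classes strongly", {
  ts <- generate_dataset(generator_config(seed = 26L), 100)
  split <- split_indices(ts$labels, 0.8, 1)
  model <- fit_csp_model(micnn:::subset_trialset(ts, split$train))
  x <- csp_feature_matrix(ts, model)
  f1 <- split(x[, 1], ts$labels)
  pooled_se <- sqrt(var(f1$left) / length(f1$left) +
                      var(f1$right) / length(f1$right))
  expect_gt(abs(mean(f1$left) - mean(f1$right)), 3 * pooled_se)
})
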