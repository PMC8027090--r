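test_that("architecture validation rejects collapsing convolution chains", {
  a <- cnn_architecture(4)
  expect_identical(micnn:::conv_chain_lengths(a), c(4L, 3L, 2L))
  expect_error(cnn_architecture(4, kernel_lengths = c(3, 3)),
               class = "micnn_config_error")
  expect_error(cnn_architecture(4, n_classes = 3),
               class = "micnn_config_error")
  expect_error(cnn_architecture(4, pool_modes = c("max", "median")),
               class = "micnn_config_error")
})

test_that("initialization honors the bounds, the constant bias and the seed", {
  arch <- cnn_architecture(4)
  p <- init_parameters(arch, 5)
  for (l in p$conv) {
    expect_lte(max(abs(l$W)), 0.3)
    expect_true(all(l$b == 0.1))
  }
  for (l in p$dense) {
    expect_lte(max(abs(l$W)), 0.3)
    expect_true(all(l$b == 0.1))
  }
  expect_identical(p, init_parameters(arch, 5))
  expect_false(identical(p, init_parameters(arch, 6)))
})

test_that("conv_forward matches the literal triple-sum with ReLU", {
  expect_equal(conv_forward(c(1, 2, 3), c(1, 1), 0)$feature_maps,
               matrix(c(3, 5), 1))
  expect_equal(conv_forward(c(1, -2, 3), c(1, 0), 0)$feature_maps,
               matrix(c(1, 0), 1))
  set.seed(30)
  for (i in 1:10) {
    D <- sample(1:3, 1); L <- sample(5:12, 1)
    K <- sample(1:4, 1); Fk <- sample(1:min(4, L), 1)
    input <- matrix(rnorm(D * L), D)
    kernels <- array(rnorm(K * D * Fk), c(K, D, Fk))
    bias <- rnorm(K)
    got <- conv_forward(input, kernels, bias)$feature_maps
    expect_equal(got, naive_conv(input, kernels, bias), tolerance = 1e-12)
  }
  # linearity over input depth
  x2 <- matrix(rnorm(2 * 8), 2)
  k2 <- array(rnorm(2 * 2 * 3), c(1, 2, 3))
  part1 <- conv_forward(x2[1, , drop = FALSE],
                        k2[, 1, , drop = FALSE], 0, "linear")$feature_maps
  part2 <- conv_forward(x2[2, , drop = FALSE],
                        k2[, 2, , drop = FALSE], 0, "linear")$feature_maps
  expect_equal(conv_forward(x2, k2, 0, "linear")$feature_maps, part1 + part2,
               tolerance = 1e-12)
  expect_error(conv_forward(c(1, 2), c(1, 1, 1), 0),
               class = "micnn_shape_error")
})

test_that("dense layers apply tanh and softmax as specified", {
  expect_equal(dense_forward(c(0, 0), matrix(0, 2, 3), rep(0, 3)),
               rep(0, 3))
  expect_equal(dense_forward(0.5, matrix(1), 0), tanh(0.5))
  expect_equal(dense_forward(c(1, 1), diag(2), c(0, 0), "softmax"),
               c(0.5, 0.5))
  expect_error(dense_forward(c(1, 2, 3), diag(2), c(0, 0)),
               class = "micnn_shape_error")
})

test_that("squared-error loss follows its definition", {
  expect_identical(sse_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(sse_loss(c(0.5, 0.5), c(1, 0)), 0.5)
  set.seed(31)
  Y <- matrix(runif(10), 5)
  expect_gte(sse_loss(Y, matrix(0, 5, 2)), 0)
  expect_error(sse_loss(c(1, 0), c(1, 0, 0)), class = "micnn_shape_error")
})

test_that("pooling forward/backward route and conserve deltas", {
  pf <- pool_forward(c(1, 7, 2, 2), 2, "max")
  expect_equal(pf$out, c(7, 2))
  expect_equal(pool_backward(c(5, 3), "max", pf$trace), c(0, 5, 3, 0))
  # ties break toward the lowest index
  pt <- pool_forward(c(4, 4), 2, "max")
  expect_equal(pool_backward(1, "max", pt$trace), c(1, 0))
  pa <- pool_forward(c(1, 3), 2, "average")
  expect_equal(pa$out, 2)
  expect_equal(pool_backward(4, "average", pa$trace), c(2, 2))
  # conservation on random batches, both modes
  set.seed(32)
  x <- array(rnorm(3 * 2 * 8), c(3, 2, 8))
  for (mode in c("max", "average")) {
    pf <- pool_forward(x, 2, mode)
    delta <- array(rnorm(length(pf$out)), dim(pf$out))
    expect_equal(sum(pool_backward(delta, mode, pf$trace)), sum(delta),
                 tolerance = 1e-12)
  }
  expect_error(pool_backward(c(1, 2), "average", pf$trace),
               class = "micnn_shape_error")
})

test_that("inverted dropout keeps expectations and disables at inference", {
  expect_true(all(dropout_mask(c(10, 10), 0) == 1))
  m <- dropout_mask(c(50, 50), 0.5)
  expect_true(all(m %in% c(0, 2)))
  expect_error(dropout_mask(c(2, 2), 1), class = "micnn_input_error")
  # expected activation is preserved: average over 1e4 masks
  set.seed(33)
  y <- runif(20)
  draws <- replicate(1e4, mean(y * dropout_mask(20, 0.5)))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean(y)), 3 * se)
  # inference path is deterministic (no dropout applied)
  arch <- cnn_architecture(4)
  p <- init_parameters(arch, 1)
  x <- matrix(rnorm(4), 1)
  expect_identical(cnn_forward(p, arch, x)$probs,
                   cnn_forward(p, arch, x)$probs)
})

test_that("the learning-rate schedule interpolates its printed endpoints", {
  cfg <- training_config()
  expect_identical(lr_at(0, cfg), 0.02)
  expect_equal(lr_at(1e6, cfg), 0.0002, tolerance = 1e-9)
  expect_equal(lr_at(1000, cfg), 0.0002 + 0.0198 * exp(-1), tolerance = 1e-12)
  expect_true(all(diff(lr_at(seq(0, 20000, by = 100), cfg)) < 0))
  expect_error(lr_at(-1, cfg), class = "micnn_input_error")
})

test_that("gradient-descent updates move every parameter by eta * gradient", {
  arch <- cnn_architecture(4)
  p <- init_parameters(arch, 2)
  zero <- cnn_backward(cnn_forward(p, arch, matrix(0.1 * 1:4, 1)), p, arch,
                       cnn_forward(p, arch, matrix(0.1 * 1:4, 1))$probs)
  # R = Y makes the squared error stationary: parameters unchanged
  expect_equal(sgd_step(p, zero, 0.1), p, tolerance = 1e-15)
  g2 <- zero
  for (l in seq_along(g2$conv)) {
    g2$conv[[l]]$W[] <- 2
    g2$conv[[l]]$b[] <- 2
  }
  for (l in seq_along(g2$dense)) {
    g2$dense[[l]]$W[] <- 2
    g2$dense[[l]]$b[] <- 2
  }
  stepped <- sgd_step(p, g2, 0.1)
  expect_equal(stepped$conv[[1]]$W, p$conv[[1]]$W - 0.2, tolerance = 1e-15)
  expect_equal(stepped$dense[[2]]$b, p$dense[[2]]$b - 0.2, tolerance = 1e-15)
  expect_error(sgd_step(p, g2, 0), class = "micnn_input_error")
})

test_that("predictions are proper probabilities with deterministic ties", {
  arch <- cnn_architecture(4)
  p <- init_parameters(arch, 3)
  x <- matrix(rnorm(20), 5)
  pred <- predict_cnn(p, arch, x)
  expect_equal(rowSums(pred$probabilities), rep(1, 5), tolerance = 1e-12)
  expect_s3_class(pred$label, "factor")
  # equal scores -> (0.5, 0.5) and the tie resolves to "left"
  sym <- p
  sym$dense[[2]]$W[] <- 0
  sym$dense[[2]]$b[] <- 0.1
  ps <- predict_cnn(sym, arch, x)
  expect_true(all(ps$probabilities == 0.5))
  expect_true(all(ps$label == "left"))
  expect_error(predict_cnn(p, arch, matrix(0, 1, 5)),
               class = "micnn_shape_error")
})
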