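test_that("the stratified 8:2 split reproduces the experiment's pool sizes", {
  labels <- rep(c("left", "right"), each = 4300)
  sp <- split_indices(labels, 0.8, seed = 1)
  expect_length(sp$train, 6880)
  expect_length(sp$validation, 1720)
  expect_equal(as.integer(table(labels[sp$train])), c(3440L, 3440L))
  # partition contract
  expect_identical(sort(c(sp$train, sp$validation)), seq_along(labels))
  expect_length(intersect(sp$train, sp$validation), 0)
  # tiny case
  sp10 <- split_indices(rep(c("left", "right"), 5), 0.8, seed = 2)
  expect_length(sp10$train, 8)
  expect_length(sp10$validation, 2)
  # reproducibility and error handling
  expect_identical(sp, split_indices(labels, 0.8, seed = 1))
  expect_error(split_indices(c("left", "left", "right"), 0.8, 1),
               class = "micnn_input_error")
  expect_error(split_indices(labels, 1.2, 1), class = "micnn_input_error")
})

test_that("training reduces the loss monotonically on a separable toy set", {
  toy <- toy_features(16)
  arch <- cnn_architecture(4)
  cfg <- training_config(batch_size = 32, n_iterations = 50, log_every = 1,
                         dropout_rate = 0, seed = 4)
  model <- train_cnn(toy$x, toy$y, arch, cfg)
  expect_true(all(diff(model$curve$train_error) <= 1e-9))
})

test_that("training is deterministic and logs a well-formed learning curve", {
  toy <- toy_features(8, seed = 5)
  arch <- cnn_architecture(4)
  cfg <- training_config(batch_size = 8, n_iterations = 40, log_every = 10,
                         seed = 9)
  m1 <- train_cnn(toy$x, toy$y, arch, cfg)
  m2 <- train_cnn(toy$x, toy$y, arch, cfg)
  expect_identical(m1$curve, m2$curve)
  expect_identical(m1$params, m2$params)
  expect_true(all(diff(m1$curve$iteration) > 0))
  expect_identical(tail(m1$curve$iteration, 1), 40L)
  expect_named(m1$curve, c("iteration", "lr", "train_error", "train_acc",
                           "val_error", "val_acc"))
  expect_error(train_cnn(toy$x[0, , drop = FALSE], character(0), arch, cfg),
               class = "micnn_input_error")
})

test_that("a net trained to zero error reproduces its training points", {
  toy <- toy_features(2, seed = 6, spread = 0.05)
  arch <- cnn_architecture(4)
  cfg <- training_config(batch_size = 4, n_iterations = 400, log_every = 400,
                         dropout_rate = 0, seed = 10)
  model <- train_cnn(toy$x, toy$y, arch, cfg)
  pred <- predict_cnn(model$params, arch, toy$x)
  expect_identical(as.character(pred$label), toy$y)
})

test_that("confusion metrics follow their definitions", {
  perfect <- metrics_from_counts(10, 0, 0, 10)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  m <- metrics_from_counts(3, 1, 1, 5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$discrimination, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-10)
})

test_that("rank-sum AUC counts concordant pairs with ties at one half", {
  expect_equal(auc_rank(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(auc_rank(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)
  expect_error(auc_rank(c(1, 2), c(TRUE, TRUE)), class = "micnn_input_error")
})

test_that("metrics agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  set.seed(50)
  for (i in 1:100) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (counts[1] + counts[3] == 0 || counts[2] + counts[4] == 0 ||
        counts[1] + counts[2] == 0) next
    m <- metrics_from_counts(counts[1], counts[2], counts[3], counts[4])
    n <- sum(counts)
    expect_equal(m$accuracy, (counts[1] + counts[4]) / n, tolerance = 1e-10)
    expect_equal(m$sensitivity, counts[1] / (counts[1] + counts[3]),
                 tolerance = 1e-10)
    expect_equal(m$specificity, counts[4] / (counts[4] + counts[2]),
                 tolerance = 1e-10)
  }
  for (i in 1:20) {
    n <- sample(10:40, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)       # rounding forces ties
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(response = labels, predictor = scores,
                          direction = "<", quiet = TRUE))))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("evaluate_model reports a coherent confusion matrix and AUC", {
  toy <- toy_features(10, seed = 7)
  arch <- cnn_architecture(4)
  cfg <- training_config(batch_size = 10, n_iterations = 300, log_every = 300,
                         dropout_rate = 0, seed = 11)
  model <- train_cnn(toy$x, toy$y, arch, cfg)
  rep <- evaluate_model(model, x = toy$x, y = toy$y)
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, length(toy$y))
  expect_equal(rep$accuracy,
               (rep$tp + rep$tn) / length(toy$y), tolerance = 1e-12)
  expect_true(all(unlist(rep[c("accuracy", "precision", "sensitivity",
                               "specificity", "auc")]) >= 0))
  expect_true(all(unlist(rep[c("accuracy", "precision", "sensitivity",
                               "specificity", "auc")]) <= 1))
  expect_error(evaluate_model(model, x = toy$x, y = rep("left", 40)),
               class = "micnn_input_error")
})

test_that("kernel sweeps skip invalid lengths and are deterministic", {
  toy <- toy_features(20, seed = 8)
  arch <- cnn_architecture(4)
  cfg <- training_config(batch_size = 16, n_iterations = 150, log_every = 150,
                         seed = 12)
  expect_warning(
    res <- kernel_size_sweep(toy$x, toy$y, c(2, 2, 3), arch, cfg),
    "skipped")
  expect_identical(res$kernel_lengths, c(2L, 2L, 3L))
  expect_true(is.na(res$accuracy_per_length[3]))   # 4 -> 2 -> 0 collapses
  expect_identical(res$accuracy_per_length[1], res$accuracy_per_length[2])
  expect_true(all(res$accuracy_per_length[1:2] >= 0 &
                    res$accuracy_per_length[1:2] <= 1))
  expect_identical(res$best_length, 2L)
})

test_that("time-segment analysis localizes imagery confined to 0-2 s", {
  cfg <- generator_config(imagery_onset_s = 0, imagery_duration_s = 2,
                          seed = 33L)
  ts <- generate_dataset(cfg, 60)
  res <- time_segment_analysis(
    ts, training_config(batch_size = 32, n_iterations = 600, log_every = 600,
                        seed = 13))
  expect_length(res$mean_accuracy_per_segment, 3)
  expect_identical(res$segment_bounds_s, list(c(0, 2), c(2, 4), c(4, 6)))
  expect_identical(which.max(res$mean_accuracy_per_segment), 1L)
  short <- micnn:::crop_trialset(ts, 0, 3)
  expect_error(time_segment_analysis(short), class = "micnn_input_error")
})
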