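#' Stratified train/validation split
#'
#' Shuffles within each class and assigns `train_fraction` of the samples to
#' the training partition, rounding per class so that the total training
#' size equals `round(train_fraction * n)` (an 8,600-sample pool at 8:2
#' yields exactly 6,880 / 1,720). The partition is disjoint, exhaustive and
#' reproducible from `seed`.
#'
#' @param labels Factor or character vector of class labels.
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param stratified Preserve class proportions (default `TRUE`).
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_indices <- function(labels, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    mi_input_error("train_fraction must lie strictly between 0 and 1")
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    mi_input_error("every class needs at least 2 samples to split")
  n <- length(labels)
  target_train <- round(train_fraction * n)
  set.seed(as.integer(seed))
  if (!stratified) {
    perm <- sample.int(n)
    return(list(train = sort(perm[seq_len(target_train)]),
                validation = sort(perm[-seq_len(target_train)])))
  }
  counts <- table(labels)
  raw <- as.numeric(counts) * train_fraction
  base <- floor(raw)
  # distribute the remainder by largest fractional part to hit the total
  short <- target_train - sum(base)
  if (short > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(short)]] <- base[order_frac[seq_len(short)]] + 1
  }
  train <- integer(0)
  for (i in seq_along(counts)) {
    idx <- which(labels == names(counts)[i])
    take <- sample(idx, length(idx))[seq_len(base[i])]
    train <- c(train, take)
  }
  list(train = sort(train), validation = sort(setdiff(seq_len(n), train)))
}

#' Train the 1-D CNN by mini-batch gradient descent
#'
#' Shuffles the training rows each epoch, consumes full mini-batches of
#' `config$batch_size`, applies the decaying learning rate of [lr_at()] at
#' every iteration and inverted dropout at F4, and logs the learning curve
#' (mean squared-error loss and accuracy on the training and optional
#' validation sets) every `config$log_every` iterations. Fully
#' deterministic given `config$seed`.
#'
#' @param x Feature matrix `[n, N]`.
#' @param y Labels (`"left"`/`"right"`, factor or character).
#' @param arch A [cnn_architecture()] with `input_length = ncol(x)`.
#' @param config A [training_config()].
#' @param x_val,y_val Optional validation set for the learning curve.
#' @return Object of class `cnn_model`: `params`, `arch`, `config`,
#'   `curve` (data frame: iteration, lr, train_error, train_acc, val_error,
#'   val_acc), `n_iterations`.
#' @export
train_cnn <- function(x, y, arch, config = training_config(),
                      x_val = NULL, y_val = NULL) {
  if (nrow(x) < 1) mi_input_error("training set is empty")
  if (ncol(x) != arch$input_length)
    mi_shape_error("feature length does not match the architecture")
  y <- factor(y, levels = mi_classes())
  R <- as_one_hot(y, nrow(x))
  n <- nrow(x)
  bs <- min(config$batch_size, n)
  batches_per_epoch <- max(1L, n %/% bs)
  total_iter <- config$n_iterations %||% (config$epochs * batches_per_epoch)

  params <- init_parameters(arch, config$seed)
  set.seed(config$seed + 1L)       # shuffling + dropout stream
  curve <- list()
  iter <- 0L
  measure <- function(px, py) {
    probs <- cnn_forward(params, arch, px)$probs
    pred <- max.col(probs, ties.method = "first")
    c(error = sse_loss(probs, as_one_hot(py, nrow(px))),
      acc = mean(pred == as.integer(factor(py, levels = mi_classes()))))
  }
  log_row <- function() {
    tr <- measure(x, y)
    va <- if (!is.null(x_val)) measure(x_val, y_val) else c(NA_real_, NA_real_)
    curve[[length(curve) + 1L]] <<- data.frame(
      iteration = iter, lr = lr_at(iter, config),
      train_error = tr[1], train_acc = tr[2],
      val_error = va[1], val_acc = va[2])
  }
  log_row()
  while (iter < total_iter) {
    perm <- sample.int(n)
    for (bstart in seq(1L, n - bs + 1L, by = bs)) {
      if (iter >= total_iter) break
      sel <- perm[bstart:(bstart + bs - 1L)]
      trace <- cnn_forward(params, arch, x[sel, , drop = FALSE],
                           training = TRUE,
                           dropout_rate = config$dropout_rate)
      grads <- cnn_backward(trace, params, arch, R[sel, , drop = FALSE])
      params <- sgd_step(params, grads, lr_at(iter, config))
      iter <- iter + 1L
      if (iter %% config$log_every == 0L || iter == total_iter) log_row()
    }
  }
  structure(list(params = params, arch = arch, config = config,
                 curve = do.call(rbind, curve), n_iterations = iter),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("<cnn_model> %d iterations; train error %.4f, accuracy %.3f\n",
              x$n_iterations, last$train_error, last$train_acc))
  invisible(x)
}

#' @export
predict.cnn_model <- function(object, features, ...) {
  predict_cnn(object$params, object$arch, features)
}

#' Confusion-matrix metrics and rank-sum AUC
#'
#' Computes accuracy, precision (reported in the source field's tables under
#' the column name "Discrimination"), sensitivity, specificity and AUC from
#' predicted labels and class-"left" probabilities, with `"left"` as the
#' positive class. The AUC is the Mann-Whitney concordance probability of
#' the positive-class scores, ties counted one half.
#'
#' @param params,arch Trained network (or pass a `cnn_model` to
#'   [evaluate_model()]'s `model` argument).
#' @param x Feature matrix.
#' @param y True labels; both classes must be present.
#' @return Object of class `metrics_report`: accuracy, precision,
#'   discrimination (= precision), sensitivity, specificity, auc, and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_model <- function(params, arch = NULL, x, y) {
  if (inherits(params, "cnn_model")) {
    arch <- params$arch
    params <- params$params
  }
  y <- factor(y, levels = mi_classes())
  if (nlevels(droplevels(y)) < 2)
    mi_input_error("AUC is undefined on a single-class test set")
  pred <- predict_cnn(params, arch, x)
  counts <- confusion_counts(pred$label, y)
  rep <- metrics_from_counts(counts["tp"], counts["fp"],
                             counts["fn"], counts["tn"])
  rep$auc <- auc_rank(pred$probabilities[, "left"], y == "left")
  rep
}

confusion_counts <- function(pred, truth) {
  pos <- mi_classes()[1]
  c(tp = sum(pred == pos & truth == pos),
    fp = sum(pred == pos & truth != pos),
    fn = sum(pred != pos & truth == pos),
    tn = sum(pred != pos & truth != pos))
}

#' Metrics from confusion counts
#'
#' @param tp,fp,fn,tn Confusion counts with `"left"` as positive class.
#' @return A `metrics_report` (without AUC).
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  structure(list(accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = precision,
                 discrimination = precision,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 auc = NA_real_,
                 tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "metrics_report")
}

#' Rank-sum (Mann-Whitney) AUC
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param positive Logical vector marking the positive samples.
#' @return AUC in `[0, 1]`; ties counted one half.
#' @export
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) mi_input_error("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.4f, precision %.4f, ",
                     "sensitivity %.4f, specificity %.4f, AUC %.4f\n"),
              x$accuracy, x$precision, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  confusion: TP %d, FP %d, FN %d, TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, discrimination = x$discrimination,
             sensitivity = x$sensitivity, specificity = x$specificity,
             auc = x$auc, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Validation accuracy across convolution-kernel lengths
#'
#' Retrains the network once per candidate kernel length (applied to every
#' conv layer, same seed throughout) and records the validation accuracy.
#' Lengths that make the convolution chain collapse below length 1 are
#' skipped with a warning and reported as `NA`.
#'
#' @param x,y Feature matrix and labels.
#' @param lengths Integer vector of kernel lengths to try.
#' @param arch_template Architecture whose kernel lengths are overridden.
#' @param config A [training_config()].
#' @param split A [split_indices()] result; defaults to a fresh 8:2 split
#'   with `config$seed`.
#' @return Object of class `sweep_result`: `kernel_lengths`,
#'   `accuracy_per_length`, `best_length` (smallest argmax).
#' @export
kernel_size_sweep <- function(x, y, lengths, arch_template,
                              config = training_config(),
                              split = split_indices(y, 0.8, config$seed)) {
  lengths <- as.integer(lengths)
  acc <- rep(NA_real_, length(lengths))
  for (i in seq_along(lengths)) {
    arch <- tryCatch(
      cnn_architecture(input_length = arch_template$input_length,
                       n_kernels = arch_template$n_kernels,
                       kernel_lengths = rep(lengths[i],
                                            length(arch_template$n_kernels)),
                       pool_widths = arch_template$pool_widths,
                       pool_modes = arch_template$pool_modes,
                       dense_width = arch_template$dense_width,
                       loss = arch_template$loss),
      micnn_config_error = function(e) {
        warning(sprintf("kernel length %d skipped: %s", lengths[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(arch)) next
    model <- train_cnn(x[split$train, , drop = FALSE], y[split$train],
                       arch, config)
    pred <- predict_cnn(model$params, arch,
                        x[split$validation, , drop = FALSE])
    acc[i] <- mean(pred$label == y[split$validation])
  }
  best <- if (all(is.na(acc))) NA_integer_ else
    lengths[which.max(replace(acc, is.na(acc), -Inf))]
  structure(list(kernel_lengths = as.integer(lengths),
                 accuracy_per_length = acc,
                 best_length = best),
            class = "sweep_result")
}

#' Per-time-segment classification accuracy
#'
#' Slices every trial into consecutive 2 s segments (`[0, 2)`, `[2, 4)`,
#' `[4, 6)` seconds from trial start), runs the full CSP + CNN pipeline
#' independently on each segment (CSP fitted on the training split only)
#' and reports the validation accuracy per segment.
#'
#' @param trialset An `mi_trialset` with trials at least 6 s long.
#' @param config A [training_config()].
#' @param m CSP filter pairs per band.
#' @param bands Frequency bands for the CSP model.
#' @param arch_template Optional architecture template (input length is set
#'   to the CSP feature count).
#' @return Object of class `segment_result`: `segment_bounds_s` (list of
#'   `(start, end)`), `mean_accuracy_per_segment`.
#' @export
time_segment_analysis <- function(trialset, config = training_config(),
                                  m = 1L,
                                  bands = list(mu = c(8, 12),
                                               beta = c(12, 25)),
                                  arch_template = NULL) {
  dur <- ncol(trialset$trials[[1]]$samples) /
    trialset$trials[[1]]$sampling_rate_hz
  if (dur < 6) mi_input_error("trials must be at least 6 s long")
  bounds <- list(c(0, 2), c(2, 4), c(4, 6))
  split <- split_indices(trialset$labels, 0.8, config$seed)
  acc <- vapply(bounds, function(b) {
    seg <- crop_trialset(trialset, b[1], b[2] - b[1])
    train_set <- subset_trialset(seg, split$train)
    model <- fit_csp_model(train_set, bands = bands, m = m)
    x <- csp_feature_matrix(seg, model)
    arch <- if (is.null(arch_template))
      cnn_architecture(input_length = model$n_features)
    else
      cnn_architecture(input_length = model$n_features,
                       n_kernels = arch_template$n_kernels,
                       kernel_lengths = arch_template$kernel_lengths,
                       dense_width = arch_template$dense_width)
    fitted <- train_cnn(x[split$train, , drop = FALSE],
                        trialset$labels[split$train], arch, config)
    pred <- predict_cnn(fitted$params, arch,
                        x[split$validation, , drop = FALSE])
    mean(pred$label == trialset$labels[split$validation])
  }, numeric(1))
  structure(list(segment_bounds_s = bounds,
                 mean_accuracy_per_segment = acc),
            class = "segment_result")
}

# Crop every trial to [start_s, start_s + duration_s); imagery metadata is
# re-expressed relative to the new origin (clipped to the segment).
crop_trialset <- function(trialset, start_s, duration_s) {
  trials <- lapply(trialset$trials, function(tr) {
    idx <- sample_window(start_s, duration_s, tr$sampling_rate_hz,
                         ncol(tr$samples))
    tr$samples <- tr$samples[, idx, drop = FALSE]
    on0 <- max(tr$imagery_onset_s - start_s, 0)
    end0 <- min(tr$imagery_onset_s + tr$imagery_duration_s - start_s,
                duration_s)
    tr$imagery_onset_s <- min(on0, duration_s)
    tr$imagery_duration_s <- max(end0 - on0, 0)
    tr
  })
  new_trialset(trials, trialset$labels, trialset$config)
}

#' Subset a trial set by index
#'
#' @param trialset An `mi_trialset`.
#' @param idx Integer (or logical) trial indices, e.g. from
#'   [split_indices()].
#' @return The reduced `mi_trialset`.
#' @export
subset_trialset <- function(trialset, idx) {
  new_trialset(trialset$trials[idx], trialset$labels[idx], trialset$config)
}
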