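# HDF5 container layout (format_version 1.0):
#   /trials  : n_trials x 2 x n_samples (double)
#   /labels  : n_trials integer, 0 = left, 1 = right
#   root attributes: sampling_rate_hz, channel_names, imagery_onset_s,
#     imagery_duration_s, seed, format_version, label_legend,
#     generator_config (YAML string)

TRIALS_FORMAT_VERSION <- "1.0"

#' Write a trial set to an HDF5 container
#'
#' @param path Output file path (overwritten if present).
#' @param trialset An `mi_trialset`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(path, trialset) {
  if (file.exists(path)) file.remove(path)
  n <- length(trialset$trials)
  ns <- ncol(trialset$trials[[1]]$samples)
  arr <- array(0, c(n, 2, ns))
  for (i in seq_len(n)) arr[i, , ] <- trialset$trials[[i]]$samples
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "trials")
  rhdf5::h5write(as.integer(trialset$labels) - 1L, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  tr1 <- trialset$trials[[1]]
  rhdf5::h5writeAttribute(tr1$sampling_rate_hz, fid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(tr1$channel_names, fid, "channel_names")
  rhdf5::h5writeAttribute(tr1$imagery_onset_s, fid, "imagery_onset_s")
  rhdf5::h5writeAttribute(tr1$imagery_duration_s, fid, "imagery_duration_s")
  rhdf5::h5writeAttribute(trialset$config$seed %||% NA_integer_, fid, "seed")
  rhdf5::h5writeAttribute(TRIALS_FORMAT_VERSION, fid, "format_version")
  rhdf5::h5writeAttribute("0=left,1=right", fid, "label_legend")
  rhdf5::h5writeAttribute(yaml::as.yaml(unclass(trialset$config)), fid,
                          "generator_config")
  invisible(path)
}

#' Read a trial set from an HDF5 container
#'
#' Validates the layout and fails with a format error naming the missing
#' dataset or attribute.
#'
#' @param path Path to a container written by [write_trials()].
#' @return An `mi_trialset`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) mi_input_error(sprintf("no such file: %s", path))
  present <- rhdf5::h5ls(path)$name
  for (ds in c("trials", "labels"))
    if (!ds %in% present)
      mi_format_error(sprintf("container is missing dataset \"/%s\"", ds))
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (at in c("sampling_rate_hz", "imagery_onset_s", "imagery_duration_s",
               "format_version"))
    if (is.null(attrs[[at]]))
      mi_format_error(sprintf("container is missing attribute \"%s\"", at))
  if (!identical(as.character(attrs$format_version), TRIALS_FORMAT_VERSION))
    mi_format_error(sprintf(
      "format_version \"%s\" is not the supported \"%s\"",
      as.character(attrs$format_version), TRIALS_FORMAT_VERSION))
  arr <- rhdf5::h5read(path, "trials")
  labels01 <- as.integer(rhdf5::h5read(path, "labels"))
  if (dim(arr)[1] != length(labels01))
    mi_format_error("/trials first dimension does not match /labels length")
  cfg <- tryCatch({
    lst <- yaml::yaml.load(attrs$generator_config)
    structure(lst, class = "generator_config")
  }, error = function(e) NULL)
  channels <- as.character(attrs$channel_names %||% c("C3", "C4"))
  trials <- lapply(seq_len(dim(arr)[1]), function(i) {
    structure(list(samples = matrix(arr[i, , ], nrow = 2,
                                    dimnames = list(channels, NULL)),
                   channel_names = channels,
                   label = mi_classes()[labels01[i] + 1L],
                   sampling_rate_hz = as.numeric(attrs$sampling_rate_hz),
                   imagery_onset_s = as.numeric(attrs$imagery_onset_s),
                   imagery_duration_s = as.numeric(attrs$imagery_duration_s)),
              class = "mi_trial")
  })
  new_trialset(trials, mi_classes()[labels01 + 1L], cfg)
}

#' Serialize feature tensors for a trial set
#'
#' Writes one 4-d array `n_trials x n_freq x n_time x 2` under
#' `/features/<kind>` with axis-label attributes, or for CSP the feature
#' matrix under `/features/csp` together with the filters (`/csp/...`).
#'
#' @param path HDF5 file (created or extended).
#' @param trialset An `mi_trialset`.
#' @param kind `"stft"`, `"cwt"` or `"csp"`.
#' @param ... Extra arguments for the feature extractor ([fit_csp_model()]
#'   arguments for `"csp"`).
#' @return `path`, invisibly.
#' @export
write_features <- function(path, trialset, kind = c("csp", "stft", "cwt"),
                           ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  present <- rhdf5::h5ls(path)
  if (!"features" %in% present$name[present$group == "/"])
    rhdf5::h5createGroup(path, "features")
  if (kind == "csp") {
    model <- fit_csp_model(trialset, ...)
    feats <- csp_feature_matrix(trialset, model)
    rhdf5::h5write(feats, path, "features/csp")
    write_csp_model(path, model)
  } else {
    fun <- if (kind == "stft") stft_feature_tensor else cwt_feature_tensor
    tensors <- lapply(trialset$trials, fun)
    d <- dim(tensors[[1]]$values)
    arr <- array(0, c(length(tensors), d))
    for (i in seq_along(tensors)) arr[i, , , ] <- tensors[[i]]$values
    rhdf5::h5write(arr, path, paste0("features/", kind))
  }
  invisible(path)
}

write_csp_model <- function(path, model) {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  present <- rhdf5::h5ls(path)
  if (!"csp" %in% present$name[present$group == "/"])
    rhdf5::h5createGroup(path, "csp")
  for (bn in names(model$bands))
    rhdf5::h5write(model$filters_per_band[[bn]], path,
                   paste0("csp/filters_", bn))
  rhdf5::h5write(yaml::as.yaml(list(
    bands = model$bands, m = model$m,
    sampling_rate_hz = model$sampling_rate_hz)), path, "csp/meta")
  invisible(path)
}

read_csp_model <- function(path) {
  meta <- yaml::yaml.load(rhdf5::h5read(path, "csp/meta"))
  filters <- lapply(names(meta$bands), function(bn)
    rhdf5::h5read(path, paste0("csp/filters_", bn)))
  names(filters) <- names(meta$bands)
  structure(list(bands = lapply(meta$bands, as.numeric),
                 m = as.integer(meta$m),
                 filters_per_band = filters,
                 eigenvalues_per_band = NULL,
                 sampling_rate_hz = as.numeric(meta$sampling_rate_hz),
                 n_features = as.integer(2 * meta$m * length(meta$bands))),
            class = "csp_model")
}

#' Save / load a trained model bundle
#'
#' Stores the network weights (`/model/...`), the architecture and training
#' configuration (YAML) and the accompanying CSP model in one HDF5 file.
#'
#' @param path Output file.
#' @param model A `cnn_model` from [train_cnn()].
#' @param csp_model The [fit_csp_model()] used to build its features.
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(path, model, csp_model) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "model")
  rhdf5::h5write(flatten_params(model$params), path, "model/theta")
  rhdf5::h5write(yaml::as.yaml(unclass(model$arch)), path, "model/arch")
  rhdf5::h5write(yaml::as.yaml(unclass(model$config)), path, "model/config")
  write_csp_model(path, csp_model)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  arch_l <- yaml::yaml.load(rhdf5::h5read(path, "model/arch"))
  arch <- cnn_architecture(input_length = arch_l$input_length,
                           n_kernels = arch_l$n_kernels,
                           kernel_lengths = arch_l$kernel_lengths,
                           pool_widths = arch_l$pool_widths,
                           pool_modes = arch_l$pool_modes,
                           dense_width = arch_l$dense_width,
                           loss = arch_l$loss)
  cfg_l <- yaml::yaml.load(rhdf5::h5read(path, "model/config"))
  config <- training_config(batch_size = cfg_l$batch_size,
                            epochs = cfg_l$epochs,
                            lr_start = cfg_l$lr_start, lr_end = cfg_l$lr_end,
                            decay_speed = cfg_l$decay_speed,
                            dropout_rate = cfg_l$dropout_rate,
                            seed = cfg_l$seed,
                            n_iterations = cfg_l$n_iterations,
                            log_every = cfg_l$log_every)
  template <- init_parameters(arch, 0L)
  params <- unflatten_params(template,
                             as.numeric(rhdf5::h5read(path, "model/theta")))
  list(model = structure(list(params = params, arch = arch, config = config,
                              curve = NULL, n_iterations = NA_integer_),
                         class = "cnn_model"),
       csp_model = read_csp_model(path))
}

# Known run-configuration keys per section; unknown keys are rejected.
run_config_schema <- function() {
  list(generator = setdiff(names(formals(generator_config)), ""),
       feature = c("kind", "m", "bands"),
       architecture = c("n_kernels", "kernel_lengths", "pool_widths",
                        "pool_modes", "dense_width", "loss"),
       training = setdiff(names(formals(training_config)), ""),
       evaluation = c("positive_class"))
}

#' Read and validate a run configuration file
#'
#' The file is YAML with up to five sections (`generator`, `feature`,
#' `architecture`, `training`, `evaluation`); every key must be known.
#'
#' @param path YAML file path.
#' @return Named list of sections (missing sections are empty lists).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mi_input_error(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  schema <- run_config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad))
    mi_config_error(sprintf("unknown config section(s): %s",
                            paste(bad, collapse = ", ")))
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(unknown))
      mi_config_error(sprintf("unknown key(s) in section \"%s\": %s", sec,
                              paste(unknown, collapse = ", ")))
  }
  out <- lapply(names(schema), function(sec) raw[[sec]] %||% list())
  names(out) <- names(schema)
  out
}
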