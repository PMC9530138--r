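# Dataset format, run configuration and end-to-end orchestration.
#
# On-disk dataset: a directory with manifest.json (record index, labels,
# sampling rate, config echo) and one CSV per record with columns
# time_s, ch1..ch8 holding dR/R values printed with 17 significant digits,
# so a write/read round trip is bit-exact.

#' Write a dataset directory
#'
#' @param records list of `strain_record` objects.
#' @param path directory to create (must not contain a manifest already
#'   unless `overwrite = TRUE`).
#' @param sampling_rate samples per second of the traces.
#' @param config optional configuration echoed into the manifest.
#' @param overwrite replace an existing dataset.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path, sampling_rate = 300, config = NULL,
                          overwrite = FALSE) {
  stopifnot(length(records) >= 1)
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("dataset already exists at ", path, call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("rec_%05d.csv", seq_along(records))
  for (i in seq_along(records)) {
    w <- records[[i]]$waveform
    t_s <- (seq_len(ncol(w)) - 1) / sampling_rate
    df <- data.frame(time_s = sprintf("%.17g", t_s))
    for (c in 1:8) df[[paste0("ch", c)]] <- sprintf("%.17g", w[c, ])
    utils::write.csv(df, file.path(path, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    n_records = length(records),
    sampling_rate = sampling_rate,
    files = files,
    class_id = vapply(records, function(r) r$class_id, integer(1)),
    subject_id = vapply(records, function(r) r$subject_id, integer(1)),
    session_id = vapply(records, function(r) r$session_id, integer(1)),
    rep_index = vapply(records, function(r) r$rep_index, integer(1)),
    config = if (!is.null(config)) strip_classes(config)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset directory
#'
#' Reconstructs the records in manifest order. A missing or corrupt record
#' file raises an error naming the file; an empty or manifest-less directory
#' is a validation error, never an empty list.
#'
#' @param path dataset directory written by [write_dataset()].
#' @return list of `strain_record` objects.
#' @export
read_dataset <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json found in ", path, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(manifest_path)
  if (length(manifest$files) != manifest$n_records) {
    stop("manifest is inconsistent: file list does not match n_records",
         call. = FALSE)
  }
  lapply(seq_len(manifest$n_records), function(i) {
    f <- file.path(path, manifest$files[i])
    if (!file.exists(f)) {
      stop("record file missing: ", manifest$files[i], call. = FALSE)
    }
    df <- utils::read.csv(f)
    cols <- paste0("ch", 1:8)
    if (!all(cols %in% names(df))) {
      stop("record file corrupt (expected columns ch1..ch8): ",
           manifest$files[i], call. = FALSE)
    }
    w <- t(as.matrix(df[, cols]))
    dimnames(w) <- NULL
    new_strain_record(w, manifest$class_id[i], manifest$subject_id[i],
                      manifest$session_id[i], manifest$rep_index[i])
  })
}

# Recursively drop S3 classes so nested configs serialize as plain lists.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

# Order-insensitive structural hash of a config list (FNV-1a over its
# canonical JSON form); tags every artifact a run writes.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a run configuration
#'
#' Bundles the simulation, preprocessing, model and evaluation settings; all
#' stage seeds derive from the single global seed. Round-trips losslessly
#' through YAML or JSON.
#'
#' @param sim a [sim_config()].
#' @param preprocess a [preprocess_config()].
#' @param classifier `"cnn"`, `"svm"` or `"correlation"`.
#' @param model a [conv_spec()] (used when `classifier = "cnn"`).
#' @param epochs,learning_rate,batch_size CNN training parameters.
#' @param k cross-validation folds.
#' @param seed global seed; overrides the simulation seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), preprocess = preprocess_config(),
                       classifier = c("cnn", "svm", "correlation"),
                       model = conv_spec(), epochs = 50L,
                       learning_rate = 1e-3, batch_size = 16L,
                       k = 5L, seed = 1L) {
  classifier <- match.arg(classifier)
  sim$seed <- as.integer(seed)
  structure(
    list(sim = sim, preprocess = preprocess, classifier = classifier,
         model = model, epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         k = as.integer(k), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json holding keys mirroring the
#'   [run_config()] arguments (nested `sim`, `preprocess`, `model` sections).
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$preprocess)) {
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$model)) args$model <- do.call(conv_spec, raw$model)
  for (nm in c("classifier", "epochs", "learning_rate", "batch_size", "k",
               "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(run_config, args)
}

#' Save a run configuration
#'
#' @param config a `run_config`.
#' @param path destination ending in .yaml/.yml or .json.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- strip_classes(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

run_pipeline_factory <- function(config) {
  switch(config$classifier,
    correlation = correlation_pipeline(),
    svm = svm_pipeline(),
    cnn = cnn_pipeline(config$model, epochs = config$epochs,
                       learning_rate = config$learning_rate,
                       batch_size = config$batch_size)
  )
}

#' Run an experiment end to end
#'
#' Simulate (or load), preprocess, cross-validate, and write artifacts:
#' `report.json` (fold accuracies, mean, confusion matrix, seeds, config and
#' its hash, timestamp), `confusion.csv`, and `run.log`. Identical
#' configurations produce byte-identical reports up to the timestamp line.
#'
#' @param config a [run_config()].
#' @param out_dir directory for artifacts (`NULL` to skip writing).
#' @param dataset_path optionally load records from a dataset directory
#'   instead of simulating.
#' @return the `eval_report`, invisibly, with the artifact paths attached as
#'   attribute `paths`.
#' @export
run_experiment <- function(config, out_dir = NULL, dataset_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  records <- if (!is.null(dataset_path)) {
    read_dataset(dataset_path)
  } else {
    synth_dataset(config$sim)
  }
  tensors <- preprocess_dataset(records, config$preprocess,
                                sampling_rate = config$sim$sampling_rate)
  labels <- vapply(records, function(r) r$class_id, integer(1))
  pipeline <- run_pipeline_factory(config)
  report <- cross_validate(pipeline, tensors, labels, k = config$k,
                           seed = config$seed)
  hash <- config_hash(strip_classes(config))
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(
      config = strip_classes(config),
      config_hash = hash,
      seed = config$seed,
      fold_accuracy = report$fold_accuracy,
      mean_accuracy = report$mean_accuracy,
      confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
      classes = as.integer(rownames(report$confusion)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(payload, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    conf_path <- file.path(out_dir, "confusion.csv")
    utils::write.csv(report$confusion, conf_path)
    log_path <- file.path(out_dir, "run.log")
    writeLines(c(
      sprintf("config_hash: %s", hash),
      sprintf("seed: %d", config$seed),
      sprintf("classifier: %s", config$classifier),
      sprintf("n_records: %d", length(records)),
      sprintf("mean_accuracy: %.6f", report$mean_accuracy)
    ), log_path)
    paths <- c(report = report_path, confusion = conf_path, log = log_path)
  }
  attr(report, "paths") <- paths
  invisible(report)
}
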