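# Evaluation protocols: stratified k-fold cross-validation, learning curves,
# exhaustive channel ablation, confusion matrices, transfer adaptation and
# SNR. Classifiers plug in as pipeline factories so every protocol runs
# unchanged over the CNN, the SVM and the correlation baseline.

#' Pipeline factories
#'
#' A pipeline is `function(train_x, train_labels, test_x, seed)` returning
#' predicted class ids for `test_x`; `train_x`/`test_x` are lists of
#' `signal_tensor` objects. The three factories wrap the package's
#' classifiers:
#' `correlation_pipeline()` classifies each test record by the cosine-nearest
#' training record; `svm_pipeline()` fits a linear SVM on flattened tensors;
#' `cnn_pipeline()` trains the 3D CNN.
#'
#' @param cost SVM soft-margin cost.
#' @param spec a [conv_spec()] for the CNN.
#' @param epochs,learning_rate,batch_size CNN training parameters.
#' @return a pipeline function.
#' @name pipelines
NULL

#' @rdname pipelines
#' @export
correlation_pipeline <- function() {
  function(train_x, train_labels, test_x, seed = 1L) {
    correlation_classify(t(vapply(train_x, tensor_features,
                                  numeric(length(tensor_features(train_x[[1]]))))),
                         train_labels,
                         t(vapply(test_x, tensor_features,
                                  numeric(length(tensor_features(test_x[[1]]))))))
  }
}

#' @rdname pipelines
#' @export
svm_pipeline <- function(cost = 1) {
  function(train_x, train_labels, test_x, seed = 1L) {
    d <- length(tensor_features(train_x[[1]]))
    svm_classify(t(vapply(train_x, tensor_features, numeric(d))), train_labels,
                 t(vapply(test_x, tensor_features, numeric(d))), cost = cost)
  }
}

#' @rdname pipelines
#' @export
cnn_pipeline <- function(spec = conv_spec(), epochs = 50L,
                         learning_rate = 1e-3, batch_size = 16L) {
  function(train_x, train_labels, test_x, seed = 1L) {
    shape <- dim(train_x[[1]]$values)[2:4]
    model <- build_model(spec, n_classes = length(unique(train_labels)),
                         input_shape = shape, seed = seed)
    model <- train_model(model, train_x, train_labels,
                         train_config(learning_rate, batch_size, epochs, seed))
    predict(model, test_x)$label
  }
}

#' Stratified k-fold split
#'
#' Partitions record indices into k folds whose sizes differ by at most one,
#' stratified by class: each class is spread as evenly as possible across
#' folds. Shuffling is seeded.
#'
#' @param labels integer class ids, one per record.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k integer index vectors.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k exceeds the dataset size", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  ordered_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > 1) sample(idx) else idx
    }), use.names = FALSE)
  })
  fold_of <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) sort(ordered_idx[fold_of == f]))
}

#' Confusion matrix
#'
#' @param true,pred equal-length integer vectors of class ids in
#'   `0..n_classes-1`.
#' @param n_classes number of classes.
#' @return an `n_classes` x `n_classes` count matrix; entry (i, j) counts
#'   records of true class i-1 predicted as class j-1.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  stopifnot(length(true) == length(pred))
  true <- as.integer(true); pred <- as.integer(pred)
  if (any(true < 0 | true >= n_classes | pred < 0 | pred >= n_classes)) {
    stop("labels must lie in 0..n_classes-1", call. = FALSE)
  }
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1)))
  for (i in seq_along(true)) {
    m[true[i] + 1L, pred[i] + 1L] <- m[true[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

new_eval_report <- function(fold_accuracy, confusion, seeds, config = list()) {
  structure(
    list(fold_accuracy = fold_accuracy,
         mean_accuracy = mean(fold_accuracy),
         confusion = confusion, seeds = seeds, config = config),
    class = "eval_report"
  )
}

#' K-fold cross-validation
#'
#' For each fold: train the pipeline on the remaining folds, test on the
#' fold. Reports per-fold accuracies (percent), their arithmetic mean (the
#' headline number; this differs from pooled accuracy when folds are
#' unequal), and the pooled confusion matrix. Every record is tested exactly
#' once.
#'
#' @param pipeline a pipeline function (see [pipelines]).
#' @param tensors list of `signal_tensor` objects.
#' @param labels integer class ids (0-based).
#' @param k number of folds.
#' @param seed integer seed (controls the split and per-fold training seeds).
#' @return an `eval_report`.
#' @export
cross_validate <- function(pipeline, tensors, labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  folds <- kfold_split(labels, k, seed)
  n_classes <- length(unique(labels))
  classes <- sort(unique(labels))
  acc <- numeric(k)
  true_all <- integer(0); pred_all <- integer(0)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    pred <- pipeline(tensors[train_idx], labels[train_idx],
                     tensors[test_idx], seed = derive_seed(seed, 6L, f))
    acc[f] <- 100 * mean(pred == labels[test_idx])
    true_all <- c(true_all, labels[test_idx])
    pred_all <- c(pred_all, as.integer(pred))
  }
  conf <- confusion_matrix(match(true_all, classes) - 1L,
                           match(pred_all, classes) - 1L, n_classes)
  dimnames(conf) <- list(true = classes, pred = classes)
  new_eval_report(acc, conf, seeds = seed,
                  config = list(k = k, n = length(labels)))
}

#' Learning curve with a fixed test fold
#'
#' The last of k folds of the record *groups* (a group is one repetition of
#' every word, e.g. one subject/repetition pair) is fixed as the test set;
#' for each requested size n, n groups are drawn at random from the remaining
#' pool (repeated `repeats` times), the pipeline is trained on them and
#' evaluated on the fixed fold.
#'
#' @param pipeline a pipeline function.
#' @param tensors list of `signal_tensor` objects.
#' @param labels integer class ids.
#' @param groups group id per record.
#' @param sizes integer vector of training-set sizes in groups.
#' @param repeats random redraws per size (default 5).
#' @param k folds used to set aside the test groups (default 5).
#' @param seed integer seed.
#' @return data frame with columns `size` and `mean_accuracy` (percent).
#' @export
learning_curve <- function(pipeline, tensors, labels, groups, sizes,
                           repeats = 5L, k = 5L, seed = 1L) {
  if (length(sizes) < 1) stop("sizes must be non-empty", call. = FALSE)
  labels <- as.integer(labels)
  ug <- unique(groups)
  gfolds <- kfold_split(rep(0L, length(ug)), k, seed) # plain split of groups
  test_groups <- ug[gfolds[[k]]]
  pool_groups <- setdiff(ug, test_groups)
  test_idx <- which(groups %in% test_groups)
  acc <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    n_g <- sizes[i]
    if (n_g > length(pool_groups)) {
      stop("requested size exceeds the available training pool", call. = FALSE)
    }
    reps <- vapply(seq_len(repeats), function(r) {
      pick <- with_seed(derive_seed(seed, 7L, i, r),
                        sample(pool_groups, n_g))
      train_idx <- which(groups %in% pick)
      pred <- pipeline(tensors[train_idx], labels[train_idx],
                       tensors[test_idx], seed = derive_seed(seed, 8L, i, r))
      100 * mean(pred == labels[test_idx])
    }, numeric(1))
    acc[i] <- mean(reps)
  }
  data.frame(size = sizes, mean_accuracy = acc)
}

#' Zero a subset of channels in raw records
#'
#' @param records list of `strain_record` objects.
#' @param keep integer channels (1..8) to keep; all others are zeroed.
#' @return list of masked records.
#' @export
mask_channels <- function(records, keep) {
  stopifnot(all(keep %in% 1:8))
  drop <- setdiff(1:8, keep)
  lapply(records, function(r) {
    r$waveform[drop, ] <- 0
    r
  })
}

#' Channel ablation over all n-channel subsets
#'
#' For every subset S of size n of the 8 channels, the complement is zeroed
#' in the raw records, the data are re-preprocessed, the pipeline is
#' retrained on a fixed stratified split and evaluated; the C(8, n)
#' accuracies are averaged. With `retrain = FALSE` one model is trained on
#' the full data and only the test records are masked (a cheap variant).
#'
#' @param records list of `strain_record` objects.
#' @param n_channels subset size n in 1..8.
#' @param pipeline a pipeline function.
#' @param preproc a [preprocess_config()].
#' @param sampling_rate input sampling rate in Hz.
#' @param k the train/test split holds out fold 1 of k (default 5).
#' @param seed integer seed (same split for every subset).
#' @param retrain retrain per subset (default TRUE).
#' @return a list with `subsets` (n x C(8,n) matrix of channel indices),
#'   `accuracy` (percent, one per subset) and `mean_accuracy`.
#' @export
channel_ablation <- function(records, n_channels, pipeline,
                             preproc = preprocess_config(),
                             sampling_rate = 300, k = 5L, seed = 1L,
                             retrain = TRUE) {
  if (n_channels < 1 || n_channels > 8) {
    stop("n_channels must lie in 1..8", call. = FALSE)
  }
  labels <- vapply(records, function(r) r$class_id, integer(1))
  folds <- kfold_split(labels, k, seed)
  test_idx <- folds[[1]]
  train_idx <- setdiff(seq_along(records), test_idx)
  subsets <- utils::combn(8, n_channels)
  full_model_pred <- NULL
  if (!retrain) {
    tensors <- preprocess_dataset(records, preproc, sampling_rate)
    # train once on unmasked data; reuse for every subset
    train_x <- tensors[train_idx]
    full_pipeline_seed <- derive_seed(seed, 9L, 0L)
  }
  acc <- vapply(seq_len(ncol(subsets)), function(j) {
    keep <- subsets[, j]
    if (retrain) {
      masked <- mask_channels(records, keep)
      tensors <- preprocess_dataset(masked, preproc, sampling_rate)
      pred <- pipeline(tensors[train_idx], labels[train_idx],
                       tensors[test_idx], seed = derive_seed(seed, 9L, j))
    } else {
      masked_test <- mask_channels(records[test_idx], keep)
      test_x <- preprocess_dataset(masked_test, preproc, sampling_rate)
      pred <- pipeline(train_x, labels[train_idx], test_x,
                       seed = full_pipeline_seed)
    }
    100 * mean(pred == labels[test_idx])
  }, numeric(1))
  list(subsets = subsets, accuracy = acc, mean_accuracy = mean(acc))
}

#' Transfer adaptation to a shifted domain
#'
#' Freezes the convolutional stack of a fitted model and fine-tunes the FC
#' layers on labelled records from the shifted domain (a new subject), at one
#' tenth of the original learning rate. Reports held-out shifted-domain
#' accuracy as a function of the adaptation-set size per class, including
#' size 0 (the unadapted model).
#'
#' @param model a fitted `cnn_model`.
#' @param adapt_x,adapt_labels labelled shifted-domain records
#'   (`signal_tensor` list + integer ids); labels must be known to the model.
#' @param heldout_x,heldout_labels shifted-domain evaluation set.
#' @param sizes_per_class integer vector of adaptation sizes per class
#'   (0 entries allowed).
#' @param epochs fine-tuning epochs (default 20).
#' @param seed integer seed.
#' @return a list with `accuracy` (data frame size/accuracy in percent) and
#'   `adapted_model` (fine-tuned at the largest size).
#' @export
transfer_adapt <- function(model, adapt_x, adapt_labels,
                           heldout_x, heldout_labels,
                           sizes_per_class = c(0L, 10L), epochs = 20L,
                           seed = 1L) {
  stopifnot(inherits(model, "cnn_model"), model$fitted)
  adapt_labels <- as.integer(adapt_labels)
  heldout_labels <- as.integer(heldout_labels)
  if (!all(adapt_labels %in% model$classes)) {
    stop("adaptation set contains classes unknown to the model", call. = FALSE)
  }
  base_lr <- if (!is.null(model$train_config)) model$train_config$learning_rate else 1e-3
  mask <- list(conv = rep(FALSE, 7L), fc = rep(TRUE, 3L))
  acc <- numeric(length(sizes_per_class))
  adapted <- model
  for (i in seq_along(sizes_per_class)) {
    s <- sizes_per_class[i]
    if (s == 0L) {
      m <- model
    } else {
      pick <- with_seed(derive_seed(seed, 10L, i), {
        unlist(lapply(model$classes, function(cl) {
          idx <- which(adapt_labels == cl)
          if (length(idx) < s) stop("not enough adaptation records per class",
                                    call. = FALSE)
          sample(idx, s)
        }), use.names = FALSE)
      })
      m <- train_model(model, adapt_x[pick], adapt_labels[pick],
                       train_config(base_lr / 10, 16L, epochs,
                                    derive_seed(seed, 11L, i)),
                       update_mask = mask)
      adapted <- m
    }
    acc[i] <- 100 * mean(predict(m, heldout_x)$label == heldout_labels)
  }
  list(accuracy = data.frame(size = sizes_per_class, accuracy = acc),
       adapted_model = adapted)
}

#' Signal-to-noise ratio
#'
#' Root-mean-square amplitude of the active segment divided by that of the
#' rest segment.
#'
#' @param active numeric vector covering the articulation window.
#' @param rest numeric vector covering a quiescent window.
#' @return the RMS ratio.
#' @export
snr <- function(active, rest) {
  if (length(active) < 1 || length(rest) < 1) {
    stop("both segments must be non-empty", call. = FALSE)
  }
  rms_rest <- sqrt(mean(rest^2))
  if (rms_rest == 0) stop("rest segment has zero RMS", call. = FALSE)
  sqrt(mean(active^2)) / rms_rest
}
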