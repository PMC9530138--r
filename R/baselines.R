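# Baseline classifiers: cosine-similarity template matching and a linear SVM
# on flattened preprocessed tensors.

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-norm vector in cosine similarity", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Nearest-template classification by cosine similarity
#'
#' Each query is assigned the class of the reference vector with the highest
#' cosine similarity; ties break toward the lowest class id. References are
#' one labelled recording per class (one "reference dataset").
#'
#' @param ref_features matrix of reference vectors, one row per reference.
#' @param ref_labels integer class ids of the references.
#' @param query_features matrix of query vectors, one row per query.
#' @return integer vector of predicted class ids.
#' @export
correlation_classify <- function(ref_features, ref_labels, query_features) {
  ref_features <- as.matrix(ref_features)
  query_features <- as.matrix(query_features)
  stopifnot(nrow(ref_features) == length(ref_labels),
            ncol(ref_features) == ncol(query_features))
  ref_norm <- sqrt(rowSums(ref_features^2))
  query_norm <- sqrt(rowSums(query_features^2))
  if (any(ref_norm == 0) || any(query_norm == 0)) {
    stop("zero-norm vector in cosine similarity", call. = FALSE)
  }
  sims <- (query_features / query_norm) %*% t(ref_features / ref_norm)
  # order references by class id so which.max's first-hit rule breaks ties low
  ord <- order(ref_labels)
  sims <- sims[, ord, drop = FALSE]
  labs <- as.integer(ref_labels)[ord]
  labs[max.col(sims, ties.method = "first")]
}

#' Leave-one-group-out correlation accuracy
#'
#' Each reference group (one repetition of every word) serves in turn as the
#' template set; all remaining records are classified and the per-group
#' accuracies are averaged arithmetically.
#'
#' @param features matrix of flattened preprocessed signals, one row per record.
#' @param labels integer class ids.
#' @param groups group id per record; every group must contain each class
#'   exactly once.
#' @return a list with `group_accuracy` (named numeric) and `mean_accuracy`
#'   (both in percent).
#' @export
correlation_cv <- function(features, labels, groups) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  ug <- unique(groups)
  if (length(ug) < 2) stop("need >= 2 reference groups", call. = FALSE)
  classes <- sort(unique(labels))
  acc <- numeric(length(ug))
  names(acc) <- as.character(ug)
  for (i in seq_along(ug)) {
    ref <- groups == ug[i]
    if (!setequal(labels[ref], classes) || sum(ref) != length(classes)) {
      stop(sprintf("group '%s' must contain each class exactly once", ug[i]),
           call. = FALSE)
    }
    pred <- correlation_classify(features[ref, , drop = FALSE], labels[ref],
                                 features[!ref, , drop = FALSE])
    acc[i] <- 100 * mean(pred == labels[!ref])
  }
  list(group_accuracy = acc, mean_accuracy = mean(acc))
}

#' Linear SVM baseline
#'
#' One-vs-rest linear-kernel SVM (via e1071) on flattened preprocessed
#' signals; the conservative conventional baseline.
#'
#' @param train_features,train_labels training matrix and integer class ids.
#' @param test_features matrix of test vectors.
#' @param cost soft-margin cost parameter C (default 1).
#' @return integer vector of predicted class ids.
#' @export
svm_classify <- function(train_features, train_labels, test_features, cost = 1) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  train_labels <- as.integer(train_labels)
  if (length(unique(train_labels)) < 2) {
    stop("SVM training set must contain >= 2 classes", call. = FALSE)
  }
  fit <- e1071::svm(x = train_features, y = factor(train_labels),
                    kernel = "linear", cost = cost, scale = FALSE)
  as.integer(as.character(predict(fit, test_features)))
}
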