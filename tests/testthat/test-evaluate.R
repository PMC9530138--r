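test_that("stratified folds partition the data with balanced sizes", {
  labels <- rep(0:9, each = 10)
  folds <- kfold_split(labels, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_true(all(vapply(folds, length, integer(1)) == 20))
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(labels))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  # stratification: every class appears in every fold for balanced data
  for (f in folds) expect_equal(sort(unique(labels[f])), 0:9)
  expect_identical(folds, kfold_split(labels, 5, seed = 2))
  expect_false(identical(folds, kfold_split(labels, 5, seed = 3)))
  # uneven sizes differ by at most one
  folds2 <- kfold_split(rep(0:2, times = c(11, 7, 5)), k = 5, seed = 1)
  sizes <- vapply(folds2, length, integer(1))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(kfold_split(0:3, k = 9), "exceeds")
})

test_that("confusion matrices count true/predicted pairs", {
  m <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(m), rbind(c(1L, 1L), c(0L, 1L)))
  perfect <- confusion_matrix(0:4, 0:4, 5)
  expect_equal(unname(perfect), diag(1L, 5))
  set.seed(9)
  true <- sample(0:3, 60, replace = TRUE)
  pred <- sample(0:3, 60, replace = TRUE)
  cm <- confusion_matrix(true, pred, 4)
  expect_equal(sum(cm), 60)
  expect_equal(unname(rowSums(cm)), unname(as.integer(table(factor(true, 0:3)))))
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "0..n_classes")
})

test_that("cross-validation tests every record once and reports fold means", {
  cfg <- noiseless_config(n_classes = 5, reps = 6, seed = 29)
  ds <- synth_dataset(cfg)
  tensors <- preprocess_dataset(ds, preprocess_config(out_len = 60))
  labels <- record_labels(ds)
  rep1 <- cross_validate(correlation_pipeline(), tensors, labels, k = 5,
                         seed = 6)
  expect_length(rep1$fold_accuracy, 5)
  expect_equal(rep1$mean_accuracy, mean(rep1$fold_accuracy))
  expect_equal(sum(rep1$confusion), length(ds))
  expect_equal(rep1$mean_accuracy, 100) # separable limit
  rep2 <- cross_validate(correlation_pipeline(), tensors, labels, k = 5,
                         seed = 6)
  expect_identical(rep1$fold_accuracy, rep2$fold_accuracy)
})

test_that("learning curves cover requested sizes and grow on easy data", {
  cfg <- noiseless_config(n_classes = 4, reps = 10, seed = 37)
  ds <- synth_dataset(cfg)
  tensors <- preprocess_dataset(ds, preprocess_config(out_len = 60))
  labels <- record_labels(ds)
  groups <- vapply(ds, function(r) r$rep_index, integer(1))
  lc <- learning_curve(correlation_pipeline(), tensors, labels, groups,
                       sizes = c(1, 4), repeats = 3, seed = 3)
  expect_equal(lc$size, c(1, 4))
  expect_true(all(is.finite(lc$mean_accuracy)))
  expect_gte(lc$mean_accuracy[2], lc$mean_accuracy[1])
  expect_error(learning_curve(correlation_pipeline(), tensors, labels, groups,
                              sizes = integer(0)), "non-empty")
})

test_that("channel ablation enumerates every subset exactly once", {
  cfg <- noisy_config(n_classes = 3, reps = 4, seed = 43)
  ds <- synth_dataset(cfg)
  # counting pipeline: record the masked data signature per call
  calls <- new.env(); calls$n <- 0
  stub <- function(train_x, train_labels, test_x, seed = 1) {
    calls$n <- calls$n + 1
    rep(train_labels[1], length(test_x))
  }
  for (n_ch in c(1, 2, 7, 8)) {
    calls$n <- 0
    res <- channel_ablation(ds, n_ch, stub,
                            preproc = preprocess_config(out_len = 30),
                            seed = 1)
    expect_equal(ncol(res$subsets), choose(8, n_ch))
    expect_equal(calls$n, choose(8, n_ch))
    expect_false(any(duplicated(t(res$subsets))))
    expect_length(res$accuracy, choose(8, n_ch))
  }
  expect_error(channel_ablation(ds, 0, stub), "1..8")
  expect_error(channel_ablation(ds, 9, stub), "1..8")
})

test_that("masking zeroes exactly the complementary channels", {
  cfg <- noisy_config(n_classes = 2, reps = 1, seed = 47)
  ds <- synth_dataset(cfg)
  masked <- mask_channels(ds, keep = c(3, 4))
  expect_true(all(masked[[1]]$waveform[-(3:4), ] == 0))
  expect_identical(masked[[1]]$waveform[3:4, ], ds[[1]]$waveform[3:4, ])
})

test_that("SNR is an RMS ratio with the expected limits", {
  x <- stats::rnorm(500)
  expect_equal(snr(x, x), 1)
  expect_equal(snr(2 * x, x), 2)
  # unit-variance noise rest, sinusoid of amplitude sqrt(2) active: both RMS 1
  set.seed(77)
  rest <- stats::rnorm(1e4)
  active <- sqrt(2) * sin(2 * pi * (1:1e4) / 64)
  expect_equal(snr(active, rest), 1, tolerance = 0.05)
  expect_error(snr(active, rep(0, 10)), "zero RMS")
  expect_error(snr(numeric(0), rest), "non-empty")
})

test_that("transfer adaptation freezes conv weights and recovers accuracy", {
  # base domain: subject 1; shifted domain: subject 2 with a strong
  # placement/amplitude shift
  cfg <- sim_config(n_classes = 3, reps_per_class = 12, n_subjects = 2,
                    noise_sd = 0.05, time_jitter_sd = 0.02,
                    amp_jitter_sd = 0.05, drift_amplitude = 0.02,
                    subject_amp_sd = 0.5, subject_shift_sd = 0.1, seed = 53)
  ds <- synth_dataset(cfg)
  tensors <- preprocess_dataset(ds, preprocess_config(out_len = 60))
  labels <- record_labels(ds)
  subj <- vapply(ds, function(r) r$subject_id, integer(1))
  spec <- small_conv_spec()
  m <- build_model(spec, 3, input_shape = c(2, 4, 60), seed = 1)
  m <- train_model(m, tensors[subj == 1], labels[subj == 1],
                   train_config(1e-3, 16, 12, seed = 1))
  t2 <- which(subj == 2)
  adapt_idx <- t2[seq_len(18)]
  held_idx <- setdiff(t2, adapt_idx)
  res <- transfer_adapt(m, tensors[adapt_idx], labels[adapt_idx],
                        tensors[held_idx], labels[held_idx],
                        sizes_per_class = c(0, 6), epochs = 15, seed = 2)
  expect_equal(res$accuracy$size, c(0, 6))
  # size 0 equals the unadapted model
  unadapted <- 100 * mean(predict(m, tensors[held_idx])$label ==
                            labels[held_idx])
  expect_equal(res$accuracy$accuracy[1], unadapted)
  # conv parameters are bit-identical after adaptation
  for (l in 1:7) {
    expect_identical(res$adapted_model$params$conv[[l]], m$params$conv[[l]])
  }
  expect_false(identical(res$adapted_model$params$fc, m$params$fc))
  expect_error(transfer_adapt(m, tensors[adapt_idx],
                              rep(99L, length(adapt_idx)),
                              tensors[held_idx], labels[held_idx]),
               "unknown")
})
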