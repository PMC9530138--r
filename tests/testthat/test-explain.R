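# A small fitted model shared by the relevance-map tests.
fit_explain_model <- function() {
  cfg <- noiseless_config(n_classes = 2, reps = 8, seed = 61)
  ds <- synth_dataset(cfg)
  tensors <- preprocess_dataset(ds, preprocess_config(out_len = 60))
  labels <- record_labels(ds)
  m <- build_model(small_conv_spec(), 2, input_shape = c(2, 4, 60), seed = 6)
  m <- train_model(m, tensors, labels, train_config(1e-3, 8, 10, seed = 6))
  list(model = m, tensors = tensors, labels = labels)
}

test_that("relevance maps satisfy their contract", {
  fx <- fit_explain_model()
  for (meth in c("lrp", "grad")) {
    mp <- rcam(fx$model, fx$tensors[[1]], target_class = fx$labels[1],
               layer = 5, method = meth)
    expect_s3_class(mp, "relevance_map")
    expect_equal(dim(mp$values), c(2, 4, 60))
    expect_true(all(mp$values >= 0 & mp$values <= 1))
    expect_equal(max(mp$values), 1)
    mp2 <- rcam(fx$model, fx$tensors[[1]], target_class = fx$labels[1],
                layer = 5, method = meth)
    expect_identical(mp$values, mp2$values)
  }
  expect_error(rcam(fx$model, fx$tensors[[1]], target_class = 42, layer = 5),
               "vocabulary")
  expect_error(rcam(fx$model, fx$tensors[[1]], target_class = 0, layer = 9),
               "layer")
})

test_that("relevance rank order is invariant to positive input rescaling", {
  fx <- fit_explain_model()
  x <- fx$tensors[[2]]
  m1 <- rcam(fx$model, x, target_class = fx$labels[2], layer = 5)
  x_scaled <- x
  x_scaled$values <- x$values * 3
  m2 <- rcam(fx$model, x_scaled, target_class = fx$labels[2], layer = 5)
  # instance norm makes the network scale-covariant: map ranks agree
  expect_gt(stats::cor(as.numeric(m1$values), as.numeric(m2$values),
                       method = "spearman"), 0.99)
})

test_that("localization score is a mass fraction", {
  mk <- function(vals) {
    structure(list(values = vals, target_class = 0L, layer = 5L,
                   method = "lrp"), class = "relevance_map")
  }
  v <- array(0, dim = c(2, 4, 100))
  v[, , 41:60] <- 1
  expect_equal(localization_score(mk(v), c(0.8, 1.2), duration = 2), 1)
  u <- array(1, dim = c(2, 4, 100))
  expect_equal(localization_score(mk(u), c(0.8, 1.2), duration = 2), 0.2)
  half <- array(0, dim = c(2, 4, 100))
  half[, , 1:20] <- 1
  half[, , 41:60] <- 1
  expect_equal(localization_score(mk(half), c(0.8, 1.2), duration = 2), 0.5)
  expect_error(localization_score(mk(array(0, c(2, 4, 10))), c(0, 1), 2),
               "all-zero")
})

test_that("t-SNE separates well-separated clusters reproducibly", {
  set.seed(71)
  centers <- matrix(stats::rnorm(3 * 128, sd = 10), nrow = 3)
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rep(centers[i, ], 40), nrow = 40, byrow = TRUE) +
      matrix(stats::rnorm(40 * 128, sd = 0.5), nrow = 40)
  }))
  labels <- rep(1:3, each = 40)
  y <- tsne_embed(x, dims = 2, perplexity = 10, seed = 4, max_iter = 300)
  expect_equal(dim(y), c(120, 2))
  expect_identical(y, tsne_embed(x, dims = 2, perplexity = 10, seed = 4,
                                 max_iter = 300))
  expect_gt(silhouette_score(y, labels), 0.5)
  expect_error(tsne_embed(x[1:10, ], perplexity = 10), "perplexity")
})

test_that("silhouette scores reflect cluster structure", {
  # coincident within class, far between classes
  pts <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  labs <- rep(0:1, each = 5)
  expect_gt(silhouette_score(pts, labs), 0.99)
  # permuted labels hover near zero
  set.seed(5)
  pts2 <- matrix(stats::rnorm(200 * 2), ncol = 2)
  s <- replicate(10, silhouette_score(pts2, sample(rep(0:1, each = 100))))
  expect_lt(abs(mean(s)), 0.1)
  # one point per class in general position is still defined
  expect_true(is.finite(silhouette_score(rbind(c(0, 0), c(1, 1), c(3, 0)),
                                         0:2)))
  expect_error(silhouette_score(pts, rep(0, 10)), ">= 2")
})

test_that("features of a trained model embed better than a label-shuffled one", {
  cfg <- noisy_config(n_classes = 3, reps = 15, seed = 67, noise_sd = 0.02)
  ds <- synth_dataset(cfg)
  tensors <- preprocess_dataset(ds, preprocess_config(out_len = 60))
  labels <- record_labels(ds)
  spec <- small_conv_spec()
  m_good <- build_model(spec, 3, input_shape = c(2, 4, 60), seed = 8)
  m_good <- train_model(m_good, tensors, labels,
                        train_config(1e-3, 16, 12, seed = 8))
  set.seed(101)
  shuffled <- sample(labels)
  m_bad <- build_model(spec, 3, input_shape = c(2, 4, 60), seed = 8)
  m_bad <- train_model(m_bad, tensors, shuffled,
                       train_config(1e-3, 16, 12, seed = 8))
  sil_good <- silhouette_score(extract_features(m_good, tensors), labels)
  sil_bad <- silhouette_score(extract_features(m_bad, tensors), labels)
  expect_gt(sil_good, sil_bad)
  # same-class features are more aligned than cross-class features
  f <- extract_features(m_good, tensors)
  f <- f / pmax(sqrt(rowSums(f^2)), 1e-12)
  sims <- f %*% t(f)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  expect_gt(mean(sims[same & !is.na(same)]),
            mean(sims[!same & !is.na(same)]))
})
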