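# Model introspection: relevance-weighted class activation maps over the
# signal, t-SNE embedding of penultimate-layer features, and quantitative
# localization / clustering scores.

#' Relevance-weighted class activation map
#'
#' Propagates a contrastive class score back to a chosen conv layer and
#' builds a map over the input signal. With `method = "lrp"` (default) the
#' score (target logit against the mean competing logit) is decomposed by
#' epsilon-rule relevance propagation through the FC and conv stack (instance
#' normalization and ReLU treated as pass-through) and the layer's relevance
#' is summed over feature channels. With `method = "grad"` the gradient of
#' the target softmax probability weights the layer's activation maps
#' elementwise before channel summation. Either way the map is the positive
#' part of the relevance-weighted activations, linearly upsampled along T to
#' the input length (and broadcast along collapsed spatial axes), then
#' min-max normalized to `[0, 1]`. Both are standard instantiations of
#' relevance-weighted class activation mapping; the method used is recorded
#' in the output.
#'
#' @param model a fitted `cnn_model`.
#' @param tensor a `signal_tensor` matching the model input shape.
#' @param target_class class id to explain (must be in the model vocabulary).
#' @param layer conv layer index in 1..7 whose activations anchor the map
#'   (default 5: late enough to carry class evidence, early enough to retain
#'   at least half the temporal resolution).
#' @param method `"lrp"` or `"grad"`.
#' @return an object of class `relevance_map`: `values` (H x W x T array in
#'   `[0, 1]` aligned to the input), `target_class`, `layer`, `method`.
#' @export
rcam <- function(model, tensor, target_class, layer = 5L,
                 method = c("lrp", "grad")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "cnn_model"))
  if (!model$fitted) stop("rcam requires a fitted model", call. = FALSE)
  if (!(layer %in% 1:7)) stop("layer must lie in 1..7", call. = FALSE)
  ti <- match(as.integer(target_class), model$classes)
  if (is.na(ti)) stop("target_class is not in the model vocabulary", call. = FALSE)

  xmat <- stack_tensors(list(tensor))
  fwd <- cnn_forward(model, xmat, keep_cache = TRUE)
  act <- fwd$cache$conv[[layer]]$act # (C_layer x N_layer), single sample

  if (method == "lrp") {
    # contrastive class score: target logit against the mean competitor, so
    # relevance tracks what separates the class rather than shared signal
    k <- nrow(fwd$logits)
    w_init <- rep(-1 / (k - 1), k)
    w_init[ti] <- 1
    rel <- lrp_to_layer(model, fwd$cache, matrix(w_init * fwd$logits, ncol = 1),
                        layer)
    map_flat <- pmax(colSums(rel), 0)
  } else {
    # gradient of the target softmax probability (inherently contrastive),
    # elementwise against the activations
    probs <- softmax_cols(fwd$logits)
    dlogits <- -probs
    dlogits[ti, 1] <- dlogits[ti, 1] + 1
    dlogits <- dlogits * probs[ti, 1]
    bwd <- cnn_backward(model, fwd$cache, dlogits, grad_at_layer = layer)
    map_flat <- pmax(colSums(act * bwd$layer_act_grad), 0)
  }

  dims_l <- model$plans[[layer]]$dims_out
  map <- array(map_flat, dim = dims_l) # (H_l, W_l, T_l)
  out <- upsample_map(map, model$input_shape)
  rng <- range(out)
  if (rng[2] > rng[1]) out <- (out - rng[1]) / (rng[2] - rng[1])
  structure(list(values = out, target_class = as.integer(target_class),
                 layer = as.integer(layer), method = method),
            class = "relevance_map")
}

# Epsilon-rule relevance propagation from an initial relevance vector at the
# logits down to the activations of conv layer `layer`. Instance norm and
# ReLU pass relevance through; conv and FC layers redistribute it
# proportionally to their contributions z.
lrp_to_layer <- function(model, cache, r_init, layer, eps = 1e-6) {
  p <- model$params
  r <- r_init
  for (j in 3:1) {
    cc <- cache$fc[[j]]
    z <- cc$z
    s <- r / (z + eps * sign_nz(z))
    c_vec <- t(p$fc[[j]]$W) %*% s
    r <- cc$input * c_vec
  }
  # r is now relevance on the flattened conv7 activations
  for (l in 7:layer) {
    if (l == layer) break
    plan <- model$plans[[l]]
    r <- matrix(r, nrow = model$spec$out_channels[l], ncol = plan$nout)
    z <- cache$conv[[l]]$z
    s <- r / (z + eps * sign_nz(z))
    ccols <- t(p$conv[[l]]$W) %*% s
    rcols <- cache$conv[[l]]$cols * ccols
    r <- matrix(col2im(rcols, plan), ncol = 1)
  }
  matrix(r, nrow = model$spec$out_channels[layer],
         ncol = model$plans[[layer]]$nout)
}

sign_nz <- function(z) ifelse(z >= 0, 1, -1)

# Upsample an (H_l, W_l, T_l) map to the model input shape: linear
# interpolation along T, replication along collapsed H/W axes.
upsample_map <- function(map, input_shape) {
  dims <- dim(map)
  out <- array(0, dim = input_shape)
  t_in <- dims[3]; t_out <- input_shape[3]
  x_in <- if (t_in > 1) seq(0, 1, length.out = t_in) else 0.5
  x_out <- seq(0, 1, length.out = t_out)
  for (h in seq_len(input_shape[1])) {
    hs <- if (dims[1] == input_shape[1]) h else 1L + (h - 1L) %% dims[1]
    for (w in seq_len(input_shape[2])) {
      ws <- if (dims[2] == input_shape[2]) w else 1L + (w - 1L) %% dims[2]
      trace <- map[hs, ws, ]
      out[h, w, ] <- if (t_in > 1) {
        stats::approx(x_in, trace, xout = x_out, rule = 2)$y
      } else {
        rep(trace, t_out)
      }
    }
  }
  out
}

#' Fraction of relevance mass inside a window
#'
#' Sum of map values inside the given time window (and channel subset)
#' divided by the total map sum.
#'
#' @param map a `relevance_map`.
#' @param window numeric `c(t0, t1)` in seconds.
#' @param duration total duration in seconds spanned by the map's T axis.
#' @param channels integer subset of 1..8 (default all); cells are located
#'   with the same row/column convention as [assemble_tensor()].
#' @return a fraction in `[0, 1]`.
#' @export
localization_score <- function(map, window, duration, channels = 1:8) {
  stopifnot(inherits(map, "relevance_map"))
  if (length(window) != 2 || !(window[1] < window[2])) {
    stop("window must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  v <- map$values
  total <- sum(v)
  if (total == 0) stop("all-zero relevance map", call. = FALSE)
  t_len <- dim(v)[3]
  times <- (seq_len(t_len) - 1) * duration / t_len
  t_sel <- times >= window[1] & times < window[2]
  rows <- ifelse(channels %% 2L == 1L, 1L, 2L)
  cols <- (channels + 1L) %/% 2L
  inside <- 0
  for (i in seq_along(channels)) {
    inside <- inside + sum(v[rows[i], cols[i], t_sel])
  }
  inside / total
}

#' t-SNE embedding of feature vectors
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding with the
#' standard recipe: per-point bandwidths matched to the target perplexity by
#' binary search, symmetrized affinities, early exaggeration, and momentum
#' gradient descent. Seeded for reproducibility.
#'
#' @param features n x d numeric matrix.
#' @param dims output dimensionality (default 2).
#' @param perplexity target perplexity (default 10); requires
#'   `n >= 3 * perplexity`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations (default 500).
#' @return an n x dims matrix of embedded points.
#' @export
tsne_embed <- function(features, dims = 2L, perplexity = 10, seed = 1L,
                       max_iter = 500L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3 * perplexity) {
    stop("need at least 3 * perplexity points", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  p <- cond_probs(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    eta <- 100
    for (iter in seq_len(max_iter)) {
      pp <- if (iter <= 100) p * 4 else p # early exaggeration
      momentum <- if (iter <= 250) 0.5 else 0.8
      yd2 <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + yd2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (pp - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      gains <- pmax(0.01, ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
      inc <- momentum * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}

# Conditional affinities P_{j|i} with bandwidths tuned to the target
# perplexity by bisection on log-precision.
cond_probs <- function(d2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- d2[i, -i]
    for (try in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; probs <- w } else {
        probs <- w / sw
        h <- -sum(probs[probs > 0] * log(probs[probs > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { # entropy too high -> narrow the kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- probs
  }
  p
}

#' Mean silhouette coefficient
#'
#' Standard mean silhouette width over all points (via the cluster package),
#' quantifying how well same-class points group together in an embedding.
#'
#' @param points n x d matrix (e.g. a t-SNE embedding).
#' @param labels class id per point; at least two distinct classes.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  cl <- as.integer(factor(labels))
  k <- length(unique(cl))
  if (k < 2) stop("need >= 2 classes", call. = FALSE)
  # silhouette widths are undefined when every point is its own cluster; the
  # usual convention scores singleton clusters as 0
  if (k >= nrow(points)) return(0)
  sil <- cluster::silhouette(cl, stats::dist(points))
  mean(sil[, "sil_width"])
}
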