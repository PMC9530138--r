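# 3D convolutional word classifier.
#
# Seven 3D convolution layers (instance normalization + ReLU after each, no
# pooling) followed by three fully connected layers on the flattened Conv7
# output, trained with mini-batch Adam on softmax cross-entropy. Convolutions
# are evaluated by an im2col gather followed by one BLAS matrix multiply per
# layer and batch, which keeps desk-scale training in plain R fast and exactly
# reproducible.
#
# Tensors are stored flattened in (C, H, W, T) column-major order: a batch is
# a (C*H*W*T) x B matrix whose columns are samples.

KERNEL_TRIPLES <- list(
  default = list(kernel = c(3L, 3L, 3L), pad = c(1L, 1L, 1L), stride = c(1L, 1L, 1L)),
  conv3   = list(kernel = c(3L, 1L, 3L), pad = c(1L, 0L, 1L), stride = c(2L, 1L, 2L))
)

#' Architecture specification of the 3D CNN
#'
#' The kernel geometry is fixed: layers 1, 2 and 4-7 use kernel (3,3,3),
#' padding (1,1,1), stride (1,1,1); layer 3 downsamples with kernel (3,1,3),
#' padding (1,0,1), stride (2,1,2). Channel widths and the two hidden FC sizes
#' are configurable (the third FC layer always has `n_classes` outputs).
#'
#' @param out_channels integer vector of 7 conv output widths.
#' @param fc_hidden integer vector of 2 hidden fully-connected sizes.
#' @param axis_order how the printed kernel triples map onto tensor axes:
#'   `"HWT"` (default; triple element 1 -> H, 2 -> W, 3 -> T, so layer 3
#'   downsamples H 2->1 and T 600->300 while preserving the 4 sensor sites) or
#'   `"THW"` (the alternative reading: element 1 -> T, 2 -> H, 3 -> W).
#' @return an object of class `conv_spec`.
#' @export
conv_spec <- function(out_channels = c(8L, 16L, 16L, 32L, 32L, 64L, 64L),
                      fc_hidden = c(256L, 128L),
                      axis_order = c("HWT", "THW")) {
  axis_order <- match.arg(axis_order)
  if (length(out_channels) != 7L || any(out_channels < 1)) {
    stop("out_channels must be 7 positive integers (7 conv layers)", call. = FALSE)
  }
  if (length(fc_hidden) != 2L || any(fc_hidden < 1)) {
    stop("fc_hidden must be 2 positive integers (FC3 is the class layer)",
         call. = FALSE)
  }
  structure(
    list(out_channels = as.integer(out_channels),
         fc_hidden = as.integer(fc_hidden),
         axis_order = axis_order),
    class = "conv_spec"
  )
}

# Kernel/pad/stride for layer l, mapped onto the (H, W, T) axes.
layer_geometry <- function(spec, layer) {
  tr <- if (layer == 3L) KERNEL_TRIPLES$conv3 else KERNEL_TRIPLES$default
  if (spec$axis_order == "HWT") {
    perm <- c(1L, 2L, 3L) # element i of the triple applies to axis i of (H,W,T)
  } else {
    # triple order (T, H, W): H takes element 2, W element 3, T element 1
    perm <- c(2L, 3L, 1L)
  }
  list(kernel = tr$kernel[perm], pad = tr$pad[perm], stride = tr$stride[perm])
}

conv_out_dim <- function(n, k, p, s) (n + 2L * p - k) %/% s + 1L

#' Per-layer output shapes and flatten length
#'
#' Applies `floor((n + 2p - k)/s) + 1` along each of H, W, T for the seven
#' conv layers and reports the flattened Conv7 size feeding FC1.
#'
#' @param spec a [conv_spec()].
#' @param input_shape integer `c(H, W, T)` of the input tensor.
#' @return a list with `shapes` (data frame: layer, channels, H, W, T) and
#'   `flatten_length`.
#' @export
output_shape <- function(spec, input_shape) {
  stopifnot(inherits(spec, "conv_spec"), length(input_shape) == 3)
  dims <- as.integer(input_shape)
  shapes <- data.frame(layer = 0:7, channels = c(1L, spec$out_channels),
                       H = 0L, W = 0L, T = 0L)
  shapes[1, c("H", "W", "T")] <- dims
  for (l in 1:7) {
    g <- layer_geometry(spec, l)
    dims <- vapply(1:3, function(a) {
      conv_out_dim(dims[a], g$kernel[a], g$pad[a], g$stride[a])
    }, integer(1))
    if (any(dims < 1L)) {
      stop(sprintf("layer %d produces an empty dimension for this input", l),
           call. = FALSE)
    }
    shapes[l + 1, c("H", "W", "T")] <- dims
  }
  list(shapes = shapes,
       flatten_length = spec$out_channels[7] * prod(dims))
}

# --- im2col machinery -------------------------------------------------------

# Precompute, for one conv layer, everything needed to evaluate it on inputs
# of a fixed shape: padded-array geometry, the gather index turning a padded
# sample into the (Cin*kH*kW*kT) x Nout column matrix, and the scatter groups
# for the backward pass.
make_conv_plan <- function(cin, dims_in, geom) {
  k <- geom$kernel; p <- geom$pad; s <- geom$stride
  dims_pad <- dims_in + 2L * p
  dims_out <- vapply(1:3, function(a) conv_out_dim(dims_in[a], k[a], p[a], s[a]),
                     integer(1))
  hp <- dims_pad[1]; wp <- dims_pad[2]; tp <- dims_pad[3]

  # flat indices (1-based) of the unpadded block inside the padded array
  arr <- array(seq_len(cin * hp * wp * tp), dim = c(cin, hp, wp, tp))
  inner_idx <- as.integer(arr[, p[1] + seq_len(dims_in[1]),
                              p[2] + seq_len(dims_in[2]),
                              p[3] + seq_len(dims_in[3])])

  # column bases: flat index of element (1, h0+1, w0+1, t0+1) per output cell,
  # output cells ordered H fastest, then W, then T
  bh <- (seq_len(dims_out[1]) - 1L) * s[1]
  bw <- (seq_len(dims_out[2]) - 1L) * s[2]
  bt <- (seq_len(dims_out[3]) - 1L) * s[3]
  bases <- 1 +
    cin * (rep(bh, times = dims_out[2] * dims_out[3]) +
           hp * (rep(rep(bw, each = dims_out[1]), times = dims_out[3]) +
                 wp * rep(bt, each = dims_out[1] * dims_out[2])))

  # row offsets: (c, dh, dw, dt) with c fastest — must match the weight layout
  co <- seq_len(cin) - 1L
  dh <- seq_len(k[1]) - 1L
  dw <- seq_len(k[2]) - 1L
  dt <- seq_len(k[3]) - 1L
  offs <- rep(co, times = k[1] * k[2] * k[3]) +
    cin * (rep(rep(dh, each = cin), times = k[2] * k[3]) +
           hp * (rep(rep(dw, each = cin * k[1]), times = k[3]) +
                 wp * rep(dt, each = cin * k[1] * k[2])))

  cink <- cin * prod(k)
  nout <- prod(dims_out)
  idx <- rep(as.integer(offs), times = nout) + rep(as.integer(bases), each = cink)
  list(cin = cin, dims_in = dims_in, dims_out = dims_out, dims_pad = dims_pad,
       cink = cink, nout = nout, npad = cin * hp * wp * tp,
       inner_idx = inner_idx, idx = idx,
       scatter_groups = sort(unique(idx)))
}

# Batched gather: (D x B) input matrix -> (CinK x Nout*B) column matrix with
# one contiguous Nout-column block per sample.
im2col <- function(x, plan) {
  b <- ncol(x)
  xpad <- matrix(0, plan$npad, b)
  xpad[plan$inner_idx, ] <- x
  matrix(xpad[plan$idx, ], nrow = plan$cink, ncol = plan$nout * b)
}

# Batched scatter-add, inverse layout of im2col: returns the (D x B) gradient.
col2im <- function(dcols, plan) {
  b <- ncol(dcols) / plan$nout
  dc <- matrix(dcols, nrow = plan$cink * plan$nout, ncol = b)
  sums <- rowsum(dc, group = plan$idx, reorder = TRUE)
  dxpad <- matrix(0, plan$npad, b)
  dxpad[plan$scatter_groups, ] <- sums
  dxpad[plan$inner_idx, , drop = FALSE]
}

# --- model construction -----------------------------------------------------

#' Build an untrained 3D CNN
#'
#' Seven conv layers (instance norm + ReLU each, no pooling) and three FC
#' layers; FC1 and FC2 carry ReLU, FC3 is linear and feeds the softmax.
#' Weights use seeded He-normal initialization, so two builds with the same
#' seed are identical.
#'
#' @param spec a [conv_spec()].
#' @param n_classes number of word classes (>= 2).
#' @param input_shape integer `c(H, W, T)` (default `c(2, 4, 600)`).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `cnn_model` (unfitted).
#' @export
build_model <- function(spec = conv_spec(), n_classes,
                        input_shape = c(2L, 4L, 600L), seed = 1L) {
  stopifnot(inherits(spec, "conv_spec"))
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  shapes <- output_shape(spec, input_shape)

  plans <- vector("list", 7L)
  dims <- as.integer(input_shape)
  cin <- 1L
  for (l in 1:7) {
    plans[[l]] <- make_conv_plan(cin, dims, layer_geometry(spec, l))
    dims <- plans[[l]]$dims_out
    cin <- spec$out_channels[l]
  }

  fc_sizes <- c(shapes$flatten_length, spec$fc_hidden, as.integer(n_classes))
  params <- with_seed(seed, {
    conv <- lapply(1:7, function(l) {
      fan_in <- plans[[l]]$cink
      list(W = matrix(stats::rnorm(spec$out_channels[l] * fan_in,
                                   sd = sqrt(2 / fan_in)),
                      nrow = spec$out_channels[l]),
           b = numeric(spec$out_channels[l]))
    })
    fc <- lapply(1:3, function(j) {
      fan_in <- fc_sizes[j]
      list(W = matrix(stats::rnorm(fc_sizes[j + 1] * fan_in,
                                   sd = sqrt(2 / fan_in)),
           nrow = fc_sizes[j + 1]),
           b = numeric(fc_sizes[j + 1]))
    })
    list(conv = conv, fc = fc)
  })

  structure(
    list(spec = spec, n_classes = as.integer(n_classes),
         input_shape = as.integer(input_shape), shapes = shapes$shapes,
         flatten_length = shapes$flatten_length, plans = plans,
         params = params, eps = 1e-5, fitted = FALSE,
         classes = NULL, training_log = NULL, init_seed = as.integer(seed)),
    class = "cnn_model"
  )
}

# Stack a list of signal tensors (or plain arrays) into a (D x B) matrix.
stack_tensors <- function(tensors) {
  cols <- lapply(tensors, function(x) {
    v <- if (inherits(x, "signal_tensor")) x$values else x
    as.numeric(v)
  })
  do.call(cbind, cols)
}

instance_norm_forward <- function(z, nout, eps) {
  # z: (Cout x (nout*B)); normalize each sample's rows over its nout columns
  b <- ncol(z) / nout
  grp <- rep(seq_len(b), each = nout)
  mu <- t(rowsum(t(z), group = grp, reorder = FALSE)) / nout        # C x B
  m2 <- t(rowsum(t(z * z), group = grp, reorder = FALSE)) / nout    # C x B
  v <- m2 - mu * mu
  inv_sd <- 1 / sqrt(pmax(v, 0) + eps)
  expand <- rep(seq_len(b), each = nout)
  xhat <- (z - mu[, expand, drop = FALSE]) * inv_sd[, expand, drop = FALSE]
  list(xhat = xhat, inv_sd = inv_sd)
}

instance_norm_backward <- function(dy, xhat, inv_sd, nout) {
  b <- ncol(dy) / nout
  grp <- rep(seq_len(b), each = nout)
  m1 <- t(rowsum(t(dy), group = grp, reorder = FALSE)) / nout
  m2 <- t(rowsum(t(dy * xhat), group = grp, reorder = FALSE)) / nout
  expand <- rep(seq_len(b), each = nout)
  inv_sd[, expand, drop = FALSE] *
    (dy - m1[, expand, drop = FALSE] - xhat * m2[, expand, drop = FALSE])
}

# Full forward pass on a batch matrix. Returns logits plus (optionally) the
# caches needed for backprop and for relevance propagation.
cnn_forward <- function(model, xmat, keep_cache = FALSE) {
  b <- ncol(xmat)
  p <- model$params
  cache <- if (keep_cache) list(conv = vector("list", 7L), fc = vector("list", 3L))
  a <- xmat
  for (l in 1:7) {
    plan <- model$plans[[l]]
    cols <- im2col(a, plan)
    z <- p$conv[[l]]$W %*% cols + p$conv[[l]]$b
    nrm <- instance_norm_forward(z, plan$nout, model$eps)
    act <- nrm$xhat * (nrm$xhat > 0)
    if (keep_cache) {
      cache$conv[[l]] <- list(input = a, cols = cols, z = z,
                              xhat = nrm$xhat, inv_sd = nrm$inv_sd, act = act)
    }
    # reshape (Cout x nout*B) -> (Cout*nout x B): sample blocks are contiguous
    a <- matrix(act, nrow = nrow(act) * plan$nout, ncol = b)
    rm(cols, z, act)
  }
  for (j in 1:3) {
    z <- p$fc[[j]]$W %*% a + p$fc[[j]]$b
    act <- if (j < 3) z * (z > 0) else z
    if (keep_cache) cache$fc[[j]] <- list(input = a, z = z, act = act)
    a <- act
  }
  list(logits = a, cache = cache)
}

# Forward a large batch in fixed-size chunks to bound the im2col memory.
# Returns logits (or FC2 activations with features = TRUE) column-per-sample.
forward_in_chunks <- function(model, xmat, features = FALSE, chunk = 16L) {
  n <- ncol(xmat)
  parts <- vector("list", ceiling(n / chunk))
  for (i in seq_along(parts)) {
    take <- ((i - 1L) * chunk + 1L):min(i * chunk, n)
    fwd <- cnn_forward(model, xmat[, take, drop = FALSE], keep_cache = features)
    parts[[i]] <- if (features) fwd$cache$fc[[2]]$act else fwd$logits
  }
  do.call(cbind, parts)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Backward pass from dlogits; returns gradients in the params layout and,
# when requested, the gradient w.r.t. a chosen conv layer's activations.
cnn_backward <- function(model, cache, dlogits, grad_at_layer = 0L) {
  p <- model$params
  b <- ncol(dlogits)
  grads <- list(conv = vector("list", 7L), fc = vector("list", 3L))
  d <- dlogits
  for (j in 3:1) {
    cc <- cache$fc[[j]]
    if (j < 3) d <- d * (cc$z > 0)
    grads$fc[[j]] <- list(W = d %*% t(cc$input), b = rowSums(d))
    d <- t(p$fc[[j]]$W) %*% d
  }
  layer_act_grad <- NULL
  for (l in 7:1) {
    plan <- model$plans[[l]]
    cc <- cache$conv[[l]]
    # d arrives as (Cout*nout x B); view as (Cout x nout*B)
    d <- matrix(d, nrow = nrow(cc$xhat), ncol = plan$nout * b)
    if (l == grad_at_layer) {
      # grad-CAM wants the gradient w.r.t. the post-ReLU activations
      layer_act_grad <- d
      break
    }
    d <- d * (cc$xhat > 0)
    d <- instance_norm_backward(d, cc$xhat, cc$inv_sd, plan$nout)
    grads$conv[[l]] <- list(W = d %*% t(cc$cols), b = rowSums(d))
    if (l > 1) {
      d <- col2im(t(p$conv[[l]]$W) %*% d, plan)
    }
  }
  list(grads = grads, layer_act_grad = layer_act_grad)
}

#' Training configuration for the CNN
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 16).
#' @param epochs number of passes over the training set (default 50).
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         epochs = 50L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, mask = NULL) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (grp in names(params)) {
    for (l in seq_along(params[[grp]])) {
      if (!is.null(mask) && !mask[[grp]][l]) next
      for (nm in c("W", "b")) {
        g <- grads[[grp]][[l]][[nm]]
        state$m[[grp]][[l]][[nm]] <- beta1 * state$m[[grp]][[l]][[nm]] + (1 - beta1) * g
        state$v[[grp]][[l]][[nm]] <- beta2 * state$v[[grp]][[l]][[nm]] + (1 - beta2) * g * g
        mh <- state$m[[grp]][[l]][[nm]] / bc1
        vh <- state$v[[grp]][[l]][[nm]] / bc2
        params[[grp]][[l]][[nm]] <- params[[grp]][[l]][[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  list(params = params, state = state)
}

#' Train the 3D CNN
#'
#' Mini-batch Adam on softmax cross-entropy. The label vocabulary is the
#' sorted set of class ids present in `labels` and must have `n_classes`
#' entries. Training is a pure function of the model, data and config seed:
#' a fixed seed reproduces the training log bit for bit.
#'
#' @param model an unfitted [build_model()] output (a fitted model may be
#'   passed to continue training, e.g. for adaptation).
#' @param tensors list of `signal_tensor` objects sharing the model's shape.
#' @param labels integer class ids, one per tensor.
#' @param config a [train_config()].
#' @param update_mask optional list with logical vectors `conv` (7) and `fc`
#'   (3); `FALSE` entries are frozen (used by transfer adaptation).
#' @return a fitted `cnn_model` with a `training_log` data frame
#'   (epoch, loss, train_accuracy).
#' @export
train_model <- function(model, tensors, labels, config = train_config(),
                        update_mask = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  labels <- as.integer(labels)
  stopifnot(length(tensors) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training data must contain >= 2 classes", call. = FALSE)
  if (length(classes) != model$n_classes) {
    stop(sprintf("model expects %d classes, data has %d",
                 model$n_classes, length(classes)), call. = FALSE)
  }
  xmat <- stack_tensors(tensors)
  if (nrow(xmat) != prod(c(1L, model$input_shape))) {
    stop("tensor shape does not match the model input shape", call. = FALSE)
  }
  y <- match(labels, classes) # 1-based class index
  n <- length(y)
  params <- model$params
  state <- list(m = adam_init(params), v = adam_init(params))
  log_rows <- vector("list", config$epochs)
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 5L, epoch), sample.int(n))
    total_loss <- 0
    correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      model$params <- params
      fwd <- cnn_forward(model, xmat[, take, drop = FALSE], keep_cache = TRUE)
      probs <- softmax_cols(fwd$logits)
      bsz <- length(take)
      picked <- probs[cbind(y[take], seq_len(bsz))]
      total_loss <- total_loss + sum(-log(pmax(picked, 1e-12)))
      correct <- correct + sum(max.col(t(fwd$logits), ties.method = "first") == y[take])
      dlogits <- probs
      dlogits[cbind(y[take], seq_len(bsz))] <-
        dlogits[cbind(y[take], seq_len(bsz))] - 1
      dlogits <- dlogits / bsz
      bwd <- cnn_backward(model, fwd$cache, dlogits)
      t_step <- t_step + 1L
      upd <- adam_step(params, bwd$grads, state, config$learning_rate, t_step,
                       mask = update_mask)
      params <- upd$params
      state <- upd$state
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = total_loss / n,
                                    train_accuracy = correct / n)
  }
  model$params <- params
  model$fitted <- TRUE
  model$classes <- classes
  model$training_log <- do.call(rbind, log_rows)
  model$train_config <- config
  model
}

#' Predict word classes
#'
#' Softmax probabilities and argmax labels; ties break toward the lowest
#' class index.
#'
#' @param object a fitted `cnn_model`.
#' @param tensors list of `signal_tensor` objects (or one tensor).
#' @param ... unused.
#' @return a list with `prob` (n x n_classes matrix, columns named by class
#'   id) and `label` (integer vector of predicted class ids).
#' @export
predict.cnn_model <- function(object, tensors, ...) {
  if (!object$fitted) stop("model is not fitted", call. = FALSE)
  if (inherits(tensors, "signal_tensor")) tensors <- list(tensors)
  xmat <- stack_tensors(tensors)
  if (nrow(xmat) != prod(c(1L, object$input_shape))) {
    stop("tensor shape does not match the model input shape", call. = FALSE)
  }
  logits <- forward_in_chunks(object, xmat)
  probs <- t(softmax_cols(logits))
  colnames(probs) <- object$classes
  idx <- max.col(probs, ties.method = "first")
  list(prob = probs, label = object$classes[idx])
}

#' Penultimate-layer feature vectors
#'
#' Activations of FC2 (the input to the classification layer), used for t-SNE
#' embedding and cluster scoring.
#'
#' @param model a fitted `cnn_model`.
#' @param tensors list of `signal_tensor` objects (or one tensor).
#' @return an n x fc_hidden[2] matrix of features.
#' @export
extract_features <- function(model, tensors) {
  if (!inherits(model, "cnn_model") || !model$fitted) {
    stop("extract_features requires a fitted model", call. = FALSE)
  }
  if (inherits(tensors, "signal_tensor")) tensors <- list(tensors)
  xmat <- stack_tensors(tensors)
  t(forward_in_chunks(model, xmat, features = TRUE))
}

#' Save a model checkpoint
#'
#' Stores the architecture spec, parameters, label vocabulary and a hash of
#' the training configuration; [load_model()] restores a model whose
#' predictions match the original to floating-point identity.
#'
#' @param model a `cnn_model`.
#' @param path file path for the checkpoint.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  payload <- model
  payload$config_hash <- config_hash(list(spec = unclass(model$spec),
                                          train = if (!is.null(model$train_config))
                                            unclass(model$train_config)))
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file path written by [save_model()].
#' @return a `cnn_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cnn_model"))
  model
}
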