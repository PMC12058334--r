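# 3D convolutional flow-state classifier.
#
# Architecture: a conv-BN-ReLU stem (kernel 3x3x3, stride 1, padding 1)
# followed by stacked conv-BN-ReLU blocks, each preceded by 2x2x2 max
# pooling, then global average pooling and a small dense head with a
# softmax output.  Tensors are [C, D, H, W, B] double arrays; the conv /
# pool / ReLU kernels live in src/nn_ops.cpp.

#' Classifier architecture configuration
#'
#' @param profile `"desk"` (64-cube inputs, reduced channels, trainable
#'   on a CPU in minutes) or `"full"` (224 x 224 chunks, 24-48-96-192
#'   channel schedule).
#' @param input_shape Input tensor shape `c(channels, frames, height,
#'   width)`; channels must be 3 (replicated grayscale).
#' @param stem_filters Filters in the stem convolution.
#' @param block_channels Channel schedule of the intermediate blocks
#'   (non-decreasing); each block is preceded by a 2x2x2 max pool.
#' @param head_hidden Width of the dense layer before the softmax
#'   output.
#' @param n_classes Number of flow states (>= 2).
#' @param classes Class labels, in order.
#' @return A `model_config` object.
#' @export
model_config <- function(profile = c("desk", "full"),
                         input_shape = NULL,
                         stem_filters = NULL,
                         block_channels = NULL,
                         head_hidden = NULL,
                         n_classes = 4L,
                         classes = condition_levels()) {
  profile <- match.arg(profile)
  if (is.null(input_shape))
    input_shape <- if (profile == "desk") c(3L, 64L, 64L, 64L)
                   else c(3L, 64L, 224L, 224L)
  if (is.null(stem_filters)) stem_filters <- if (profile == "desk") 8L else 24L
  if (is.null(block_channels))
    block_channels <- if (profile == "desk") c(16L, 32L) else c(48L, 96L, 192L)
  if (is.null(head_hidden)) head_hidden <- if (profile == "desk") 32L else 128L
  if (n_classes < 2L) stopf("n_classes must be >= 2, got %d", n_classes)
  if (length(classes) != n_classes)
    stopf("classes has length %d but n_classes = %d", length(classes),
          n_classes)
  sched <- c(stem_filters, block_channels)
  if (any(diff(sched) < 0))
    stopf("channel schedule must be non-decreasing, got %s",
          paste(sched, collapse = "-"))
  if (length(input_shape) != 4L || input_shape[1] != 3L)
    stopf("input_shape must be c(3, frames, height, width)")
  structure(list(profile = profile,
                 input_shape = as.integer(input_shape),
                 stem_filters = as.integer(stem_filters),
                 stem_kernel = c(3L, 3L, 3L),
                 stem_stride = c(1L, 1L, 1L),
                 stem_padding = c(1L, 1L, 1L),
                 block_channels = as.integer(block_channels),
                 pool_spec = "2x2x2 max pool before each block",
                 head_hidden = as.integer(head_hidden),
                 n_classes = as.integer(n_classes),
                 classes = classes),
            class = "model_config")
}

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

new_conv_bn <- function(c_in, c_out) {
  list(w = he_init(c_out, c_in * 27L), b = numeric(c_out),
       gamma = rep(1, c_out), beta = numeric(c_out),
       rmean = numeric(c_out), rvar = rep(1, c_out))
}

#' Build an untrained classifier
#'
#' Instantiates the architecture of a [model_config()] with seeded
#' He-initialised weights.  Fails with a shape error if the input is too
#' small for the pooling schedule.
#'
#' @param config A [model_config()].
#' @param input_shape Input shape override, `c(3, frames, height,
#'   width)`.
#' @param seed Seed for weight initialisation.
#' @return A `flow_model` object.
#' @export
build_model <- function(config = model_config(),
                        input_shape = config$input_shape, seed = 1L) {
  dims <- as.integer(input_shape[2:4])
  for (i in seq_along(config$block_channels)) {
    if (any(dims %% 2L != 0L) || any(dims < 2L))
      stopf("pooling stage %d (before block %d): extent %s not divisible by 2",
            i, i, paste(dims, collapse = "x"))
    dims <- dims %/% 2L
  }
  with_seed(seed, {
    chans <- c(3L, config$stem_filters, config$block_channels)
    layers <- lapply(seq_len(length(chans) - 1L), function(i)
      new_conv_bn(chans[i], chans[i + 1L]))
    c_last <- chans[length(chans)]
    head <- list(
      bn_gamma = rep(1, c_last), bn_beta = numeric(c_last),
      bn_rmean = numeric(c_last), bn_rvar = rep(1, c_last),
      w1 = he_init(config$head_hidden, c_last),
      b1 = numeric(config$head_hidden),
      w2 = he_init(config$n_classes, config$head_hidden),
      b2 = numeric(config$n_classes))
    structure(list(config = config, input_shape = as.integer(input_shape),
                   layers = layers, head = head, init_seed = seed),
              class = "flow_model")
  })
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf(
    "flow_model (%s): input %s, stem %d, blocks %s, head %d -> %d classes\n",
    x$config$profile, paste(x$input_shape, collapse = "x"),
    x$config$stem_filters,
    paste(x$config$block_channels, collapse = "-"),
    x$config$head_hidden, x$config$n_classes))
  invisible(x)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# forward pass; cache retained only when train = TRUE (or grads needed)
model_forward <- function(model, x, train = FALSE, keep_cache = train) {
  caches <- list()
  h <- x
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (i > 1L) {
      pooled <- maxpool3d_fwd(h)
      if (keep_cache)
        caches[[i - 1L]]$pool <- list(idx = pooled$idx, in_dims = dim(h))
      h <- pooled$y
    }
    conv_in <- h
    conv_out <- conv3d_fwd(h, ly$w, ly$b)
    bnr <- bn_relu_fwd(conv_out, ly$gamma, ly$beta, ly$rmean, ly$rvar,
                       train, 0.1, 1e-5)
    if (train) {
      model$layers[[i]]$rmean <- bnr$rmean
      model$layers[[i]]$rvar <- bnr$rvar
    }
    h <- bnr$y
    if (keep_cache)
      caches[[i]] <- list(conv_in = conv_in, conv_out = conv_out,
                          mu = bnr$mu, inv = bnr$inv, relu_out = h)
  }
  d <- dim(h)
  n_sp <- prod(d[2:4])
  feats <- apply(h, 5, function(s) rowMeans(matrix(s, nrow = d[1])))
  feats <- matrix(feats, nrow = d[1])
  # feature batch norm: global-average-pooled channels have wildly
  # different scales, which otherwise stalls the dense head for epochs
  hd <- model$head
  if (train && ncol(feats) > 1L) {
    mu <- rowMeans(feats)
    v <- rowMeans(feats * feats) - mu^2
    model$head$bn_rmean <- 0.9 * hd$bn_rmean + 0.1 * mu
    model$head$bn_rvar <- 0.9 * hd$bn_rvar + 0.1 * v
  } else {
    mu <- hd$bn_rmean
    v <- hd$bn_rvar
  }
  bn_inv <- 1 / sqrt(v + 1e-5)
  xhat <- (feats - mu) * bn_inv
  z0 <- hd$bn_gamma * xhat + hd$bn_beta
  z1 <- hd$w1 %*% z0 + hd$b1
  a1 <- relu_fwd(z1)
  z2 <- hd$w2 %*% a1 + hd$b2
  probs <- softmax_cols(z2)
  rownames(probs) <- model$config$classes
  list(probs = probs, model = model,
       cache = if (keep_cache)
         list(layers = caches, feats = feats, xhat = xhat,
              bn_inv = bn_inv, z0 = z0, a1 = a1,
              last_dims = d, n_sp = n_sp))
}

# gradients for one batch given softmax output and one-hot targets
model_backward <- function(model, fwd, onehot) {
  b <- ncol(onehot)
  cache <- fwd$cache
  dz2 <- (fwd$probs - onehot) / b
  g <- list(head = list(
    w2 = dz2 %*% t(cache$a1), b2 = rowSums(dz2)))
  da1 <- t(model$head$w2) %*% dz2
  dz1 <- relu_bwd(da1, cache$a1)
  g$head$w1 <- dz1 %*% t(cache$z0)
  g$head$b1 <- rowSums(dz1)
  dz0 <- t(model$head$w1) %*% dz1
  g$head$bn_gamma <- rowSums(dz0 * cache$xhat)
  g$head$bn_beta <- rowSums(dz0)
  dxhat <- dz0 * model$head$bn_gamma
  dfeats <- if (b > 1L)
    (dxhat - rowMeans(dxhat) -
       cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$bn_inv
  else dxhat * cache$bn_inv
  d <- cache$last_dims
  gh <- array(0, d)
  m <- matrix(gh, nrow = d[1])
  idx_sample <- rep(seq_len(d[5]), each = cache$n_sp)
  m[] <- dfeats[, idx_sample] / cache$n_sp
  dim(m) <- d
  gh <- m
  g$layers <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    lc <- cache$layers[[i]]
    bnb <- bn_relu_bwd(gh, lc$conv_out, lc$relu_out, lc$mu, lc$inv,
                       ly$gamma)
    cb <- conv3d_bwd(lc$conv_in, ly$w, bnb$dx, need_gx = i > 1L)
    g$layers[[i]] <- list(w = cb$gw, b = cb$gb,
                          gamma = bnb$dgamma, beta = bnb$dbeta)
    if (i > 1L) {
      gh <- maxpool3d_bwd(cb$gx, cache$layers[[i - 1L]]$pool$idx,
                          cache$layers[[i - 1L]]$pool$in_dims)
    }
  }
  g
}

# stack chunks into a [3, T, H, W, B] model input tensor
batch_tensor <- function(chunks) {
  d <- dim(chunks[[1]]$frames)
  x <- array(0, dim = c(3L, d, length(chunks)))
  for (i in seq_along(chunks))
    x[, , , , i] <- to_three_channel(chunks[[i]]$frames)
  x
}

#' Class-probability predictions for a list of chunks
#'
#' Runs the model in evaluation mode (batch-norm uses running
#' statistics, so predictions are deterministic and independent of batch
#' composition).
#'
#' @param model A `flow_model`.
#' @param chunks List of chunks (see [make_chunks()]).
#' @param batch_size Chunks per forward pass.
#' @return Matrix (length(chunks) x n_classes) of probabilities; columns
#'   named by class.
#' @export
predict_chunks <- function(model, chunks, batch_size = 8L) {
  n <- length(chunks)
  out <- matrix(NA_real_, n, model$config$n_classes,
                dimnames = list(NULL, model$config$classes))
  if (n == 0L) return(out)
  d <- dim(chunks[[1]]$frames)
  if (!all(c(3L, d) == model$input_shape))
    stopf("chunk shape %s does not match model input %s",
          paste(c(3L, d), collapse = "x"),
          paste(model$input_shape, collapse = "x"))
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    fwd <- model_forward(model, batch_tensor(chunks[idx]), train = FALSE)
    out[idx, ] <- t(fwd$probs)
  }
  out
}

#' Aggregate chunk predictions into a video-level label
#'
#' Majority vote over the chunk labels of one video; ties resolve toward
#' the lower-flow class, the conservative call when screening for
#' occlusion.
#'
#' @param labels Character vector of per-chunk predicted labels.
#' @param levels Class ordering, lowest flow first.
#' @return Single video-level label.
#' @export
vote_video <- function(labels, levels = condition_levels()) {
  if (length(labels) == 0L) stopf("no chunk labels to vote over")
  counts <- table(factor(labels, levels = levels))
  winners <- names(counts)[counts == max(counts)]
  winners[1L]          # levels are ordered lowest flow first
}
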