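#' Training hyperparameters
#'
#' The training recipe: mini-batch Adam with batch size 8, 20 epochs and
#' an initial learning rate of 0.001 on categorical cross-entropy.
#' `half_precision` emulates 16-bit parameter storage by rounding every
#' parameter to IEEE binary16 after each optimizer step; it defaults to
#' off, where training is exactly reproducible given the seed.
#'
#' @param batch_size Chunks per mini-batch (>= 1).
#' @param epochs Training epochs (>= 0).
#' @param learning_rate Initial Adam learning rate (> 0).
#' @param optimizer Only `"adam"` is provided.
#' @param half_precision Round parameters to binary16 after each step.
#' @param seed Seed for weight init and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 8L, epochs = 20L,
                         learning_rate = 0.001, optimizer = "adam",
                         half_precision = FALSE, seed = 1L) {
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (epochs < 0L) stopf("epochs must be >= 0")
  check_number(learning_rate, "learning_rate", lower = 0,
               strict_lower = TRUE)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 half_precision = isTRUE(half_precision),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Categorical cross-entropy
#'
#' `L = -sum_i t_i log(p_i)` for a one-hot truth vector and a predicted
#' probability simplex.  Probabilities are floored at `1e-12` inside the
#' log for numerical safety.  Matrix inputs (classes x samples) return
#' one loss per sample.
#'
#' @param truth One-hot vector, or matrix with one-hot columns.
#' @param probs Probability vector summing to 1, or matrix of
#'   probability columns; same shape as `truth`.
#' @return Non-negative loss (vector of losses for matrix input).
#' @export
cross_entropy <- function(truth, probs) {
  if (length(truth) != length(probs) ||
      !identical(dim(truth), dim(probs)))
    stopf("truth and probs must have identical shapes")
  sums <- if (is.matrix(probs)) colSums(probs) else sum(probs)
  if (any(abs(sums - 1) > 1e-6))
    stopf("probs must sum to 1 (max deviation %g)", max(abs(sums - 1)))
  logp <- log(pmax(probs, 1e-12))
  if (is.matrix(probs)) colSums(truth * logp) * -1 else -sum(truth * logp)
}

# elementwise recursion over matched parameter / gradient trees
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map(f, a[[nm]])
    out
  } else f(a)
}

.head_param_names <- c("bn_gamma", "bn_beta", "w1", "b1", "w2", "b2")

model_params <- function(model) {
  list(layers = lapply(model$layers, function(ly)
    ly[c("w", "b", "gamma", "beta")]),
    head = model$head[.head_param_names])
}

set_model_params <- function(model, params) {
  for (i in seq_along(model$layers))
    model$layers[[i]][c("w", "b", "gamma", "beta")] <-
      params$layers[[i]]
  model$head[.head_param_names] <- params$head
  model
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(function(m, v)
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps),
    state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

one_hot <- function(labels, classes) {
  m <- matrix(0, length(classes), length(labels),
              dimnames = list(classes, NULL))
  for (i in seq_along(labels)) {
    j <- match(labels[i], classes)
    if (is.na(j)) stopf("unknown class label '%s'", labels[i])
    m[j, i] <- 1
  }
  m
}

eval_chunks <- function(model, chunks, classes, batch_size = 8L) {
  if (length(chunks) == 0L)
    return(list(loss = NA_real_, acc = NA_real_))
  probs <- predict_chunks(model, chunks, batch_size)
  labels <- vapply(chunks, `[[`, "", "label")
  truth <- one_hot(labels, classes)
  pred <- classes[max.col(probs, ties.method = "first")]
  list(loss = mean(cross_entropy(truth, t(probs))),
       acc = mean(pred == labels))
}

#' Train the flow-state classifier
#'
#' Mini-batch Adam on categorical cross-entropy over the split's
#' training chunks, with per-epoch evaluation on the validation chunks.
#' The returned model is the checkpoint with the best validation
#' accuracy (ties resolved toward the later epoch); batch-norm running
#' statistics travel with the checkpoint.
#'
#' @param model A `flow_model` from [build_model()].
#' @param split A `dataset_split` (train and val chunk lists are used).
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint), `history` (data frame
#'   with per-epoch train/val loss and accuracy) and `final_model` (the
#'   end-of-training weights).
#' @export
train_model <- function(model, split, cfg = train_config()) {
  train <- split$train
  if (length(train) == 0L) stopf("training split is empty")
  classes <- model$config$classes
  present <- unique(vapply(train, `[[`, "", "label"))
  missing <- setdiff(classes, present)
  if (length(missing) > 0L)
    stopf("training data is missing class(es): %s",
          paste(missing, collapse = ", "))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  if (cfg$epochs == 0L)
    return(list(model = model, history = history, final_model = model))

  state <- list(t = 0L,
                m = tree_map(function(p) p * 0, model_params(model)),
                v = tree_map(function(p) p * 0, model_params(model)))
  best <- list(model = model, acc = -Inf)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(length(train))
      ep_loss <- 0
      ep_correct <- 0L
      for (s in seq(1L, length(train), by = cfg$batch_size)) {
        idx <- order[s:min(length(train), s + cfg$batch_size - 1L)]
        batch <- train[idx]
        x <- batch_tensor(batch)
        labels <- vapply(batch, `[[`, "", "label")
        onehot <- one_hot(labels, classes)
        fwd <- model_forward(model, x, train = TRUE)
        model <- fwd$model                  # updated BN running stats
        grads <- model_backward(model, fwd, onehot)
        stepped <- adam_step(model_params(model), grads, state,
                             cfg$learning_rate)
        state <- stepped$state
        params <- stepped$params
        if (cfg$half_precision)
          params <- tree_map(round_half_precision, params)
        model <- set_model_params(model, params)
        ep_loss <- ep_loss +
          sum(cross_entropy(onehot, fwd$probs))
        pred <- classes[max.col(t(fwd$probs), ties.method = "first")]
        ep_correct <- ep_correct + sum(pred == labels)
      }
      val <- eval_chunks(model, split$val, classes, cfg$batch_size)
      history <- rbind(history, data.frame(
        epoch = epoch,
        train_loss = ep_loss / length(train),
        train_acc = ep_correct / length(train),
        val_loss = val$loss, val_acc = val$acc))
      score <- if (is.na(val$acc)) ep_correct / length(train) else val$acc
      if (score >= best$acc) best <- list(model = model, acc = score)
    }
  })
  list(model = best$model, history = history, final_model = model)
}
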