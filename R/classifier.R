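# The compact CNN classifier: fixed reference architecture, training
# loop, prediction and export.

#' Reference compact CNN architecture
#'
#' The fixed 204,256-parameter architecture used for species
#' classification: four convolution blocks (conv + batch norm + ReLU +
#' pooling + spatial dropout) followed by a 48-unit dense block and an
#' 8-way softmax. Kernel sizes (7, 5, 3, 3) and strides (2, 2, 1, 1) are
#' the unique combination consistent with the published output shapes and
#' per-layer parameter counts; pooling uses ceil-mode "same" semantics.
#'
#' @param input_shape Input image shape; the reference input is
#'   `112 x 170 x 3` (the semi-supervised variant narrows the width to
#'   168).
#' @param n_classes Number of species.
#' @param spatial_dropout Dropout rate applied channel-wise after each
#'   convolution block.
#' @param dropout Dropout rate after the dense block.
#' @return A [model_spec()].
#' @examples
#' spec <- build_classifier_spec()
#' count_parameters(spec)$total  # 204256
#' @export
build_classifier_spec <- function(input_shape = c(112L, 170L, 3L),
                                  n_classes = 8L,
                                  spatial_dropout = 0.05, dropout = 0.2) {
  model_spec(list(
    layer_conv2d(56L, kernel = 7L, stride = 2L),
    layer_batchnorm(),
    layer_relu(),
    layer_maxpool(2L),
    layer_spatial_dropout(spatial_dropout),
    layer_conv2d(72L, kernel = 5L, stride = 2L),
    layer_batchnorm(),
    layer_relu(),
    layer_avgpool(2L),
    layer_spatial_dropout(spatial_dropout),
    layer_conv2d(56L, kernel = 3L, stride = 1L),
    layer_batchnorm(),
    layer_relu(),
    layer_avgpool(2L),
    layer_spatial_dropout(spatial_dropout),
    layer_conv2d(72L, kernel = 3L, stride = 1L),
    layer_batchnorm(),
    layer_relu(),
    layer_avgpool(2L),
    layer_spatial_dropout(spatial_dropout),
    layer_flatten(),
    layer_dense(48L),
    layer_batchnorm(),
    layer_relu(),
    layer_dropout(dropout),
    layer_dense(as.integer(n_classes)),
    layer_softmax()
  ), input_shape = input_shape, n_classes = as.integer(n_classes))
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with a learning
#' rate of 0.003 and batches of 8, early stopping on validation loss.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before stopping (the best weights are restored).
#' @param min_delta Smallest validation-loss improvement that counts as
#'   progress for early stopping.
#' @param seed Integer seed for weight initialisation, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 0.003,
                         max_epochs = 100L, early_stop_patience = 10L,
                         min_delta = 0, seed = 0L) {
  stopifnot(batch_size >= 1, learning_rate > 0, min_delta >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

as_label0 <- function(labels, levels = NULL) {
  f <- if (is.null(levels)) as.factor(labels) else factor(labels, levels = levels)
  list(y = as.integer(f) - 1L, levels = levels(f))
}

batch_slices <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) s:min(s + batch_size - 1L, n))
}

model_accuracy <- function(model, images, y0, batch_size = 32L) {
  probs <- predict(model, images, batch_size = batch_size)
  mean(max.col(probs, ties.method = "first") - 1L == y0)
}

model_loss <- function(model, images, y0, batch_size = 32L) {
  n <- dim(images)[4]
  total <- 0
  for (sl in batch_slices(n, batch_size)) {
    fw <- nn_forward(model, images[, , , sl, drop = FALSE], training = FALSE)
    total <- total + softmax_xent(fw$logits, y0[sl])$loss * length(sl)
  }
  total / n
}

#' Train the compact classifier
#'
#' Minibatch Adam training with sparse categorical cross-entropy, a
#' held-out validation set monitored each epoch, and early stopping that
#' restores the best-validation-loss weights. All randomness (weight
#' initialisation, shuffling, dropout) is derived from `config$seed`.
#'
#' When a [stratified_split()] is supplied the training and validation
#' partitions are taken from it; `extra_train` (e.g. SMOTE synthetics
#' from [smote_oversample()]) is appended to the training partition only,
#' so validation and test data keep their natural class balance.
#'
#' @param spec A [model_spec()], typically [build_classifier_spec()].
#' @param images Array `H x W x C x N` of input images in `[0, 1]`.
#' @param labels Class label per image (factor or character).
#' @param config A [train_config()].
#' @param split Optional [stratified_split()] of `1:N`; without it, a 20%
#'   tail of a seeded shuffle is held out for validation.
#' @param extra_train Optional list with `images` and `labels` appended to
#'   the training partition.
#' @return List with `model` (an `echo_model` carrying the class levels)
#'   and `history` (one row per epoch: losses and accuracies).
#' @export
train_classifier <- function(spec, images, labels, config = train_config(),
                             split = NULL, extra_train = NULL) {
  lab <- as_label0(labels)
  n <- dim(images)[4]
  stopifnot(length(lab$y) == n)
  if (!is.null(split)) {
    tr_idx <- split$train_idx
    val_idx <- split$val_idx
  } else {
    ord <- with_seed(config$seed + 1L, sample.int(n))
    n_val <- max(1L, round(0.2 * n))
    val_idx <- ord[seq_len(n_val)]
    tr_idx <- ord[-seq_len(n_val)]
  }
  x_tr <- images[, , , tr_idx, drop = FALSE]
  y_tr <- lab$y[tr_idx]
  if (!is.null(extra_train)) {
    ex <- as_label0(extra_train$labels, levels = lab$levels)
    x_tr <- array(c(x_tr, extra_train$images),
                  dim = c(dim(images)[1:3], length(y_tr) + length(ex$y)))
    y_tr <- c(y_tr, ex$y)
  }
  if (length(unique(y_tr)) < length(lab$levels)) {
    stop_invalid("every class must appear in the training partition")
  }
  x_val <- images[, , , val_idx, drop = FALSE]
  y_val <- lab$y[val_idx]

  model <- nn_init(spec, seed = config$seed)
  model$levels <- lab$levels
  opt <- adam_init(model$params)
  history <- NULL
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  n_tr <- length(y_tr)
  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_correct <- 0
      for (sl in batch_slices(n_tr, config$batch_size)) {
        idx <- ord[sl]
        xb <- x_tr[, , , idx, drop = FALSE]
        yb <- y_tr[idx]
        fw <- nn_forward(model, xb, training = TRUE)
        model <- apply_bn_updates(model, fw$bn_updates)
        ls <- softmax_xent(fw$logits, yb)
        bw <- nn_backward(model, fw$caches, ls$dlogits)
        upd <- adam_step(model$params, bw$grads, opt, config$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + ls$loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(fw$logits, ties.method = "first") - 1L == yb)
      }
      val_loss <- model_loss(model, x_val, y_val)
      val_acc <- model_accuracy(model, x_val, y_val)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n_tr,
        train_acc = ep_correct / n_tr,
        val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss - max(config$min_delta, 1e-6)) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= config$early_stop_patience) {
        break
      }
    }
  })
  model$params <- best$params
  list(model = model, history = history)
}

#' Predict class probabilities
#'
#' @param object A trained `echo_model`.
#' @param images Array `H x W x C x N` (or a single `H x W x C` image).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return `N x n_classes` matrix of probabilities; each row is
#'   non-negative and sums to one. Columns carry class names when the
#'   model was trained on labelled data.
#' @export
predict.echo_model <- function(object, images, batch_size = 32L, ...) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  in_shape <- object$spec$input_shape
  if (!identical(dim(images)[1:3], as.integer(in_shape))) {
    stop_invalid("images must be shaped %s", paste(in_shape, collapse = "x"))
  }
  n <- dim(images)[4]
  out <- NULL
  for (sl in batch_slices(n, batch_size)) {
    fw <- nn_forward(object, images[, , , sl, drop = FALSE], training = FALSE)
    out <- rbind(out, nn_softmax(fw$logits))
  }
  if (!is.null(object$levels)) colnames(out) <- object$levels
  out
}

# ---- export --------------------------------------------------------------

quantize_array <- function(a) {
  rng <- range(a)
  scale <- (rng[2] - rng[1]) / 255
  if (scale == 0) scale <- 1
  q <- as.integer(round((a - rng[1]) / scale))
  list(q = as.raw(q), zero = rng[1], scale = scale, dim = dim(a))
}

dequantize_array <- function(qa) {
  a <- as.integer(qa$q) * qa$scale + qa$zero
  dim(a) <- qa$dim
  a
}

#' Export a trained model as a compact artifact
#'
#' Serialises the architecture and weights to a single file. With
#' `quantize = TRUE` the convolution and dense kernels are stored as
#' 8-bit integers with a per-array affine dequantisation rule (biases and
#' normalisation parameters stay at full precision), trading a small
#' accuracy cost for a much smaller artifact — the same idea behind the
#' integer formats used on embedded inference runtimes. Without
#' quantisation, [load_compact()] reproduces the model bit for bit.
#'
#' @param model A trained `echo_model`.
#' @param path Output file path.
#' @param quantize Store large kernels as 8-bit integers.
#' @return A size report: list with `bytes_full` (serialised full-precision
#'   size), `bytes_export` (bytes written) and `ratio`.
#' @export
export_compact <- function(model, path, quantize = FALSE) {
  stopifnot(inherits(model, "echo_model"))
  payload <- list(spec = model$spec, levels = model$levels,
                  quantized = quantize, params = model$params)
  bytes_full <- length(serialize(payload, NULL, xdr = FALSE))
  if (quantize) {
    payload$params <- lapply(model$params, function(p) {
      if (!is.null(p$W)) p$W <- quantize_array(p$W)
      p
    })
  }
  saveRDS(payload, path, compress = FALSE)
  size_report <- list(bytes_full = bytes_full,
                      bytes_export = as.integer(file.size(path)),
                      ratio = as.numeric(file.size(path)) / bytes_full)
  size_report
}

#' Load a model exported by [export_compact()]
#'
#' @param path Artifact path.
#' @return An `echo_model` (kernels dequantised if the artifact was
#'   quantised).
#' @export
load_compact <- function(path) {
  payload <- readRDS(path)
  params <- payload$params
  if (isTRUE(payload$quantized)) {
    params <- lapply(params, function(p) {
      if (!is.null(p$W) && is.list(p$W)) p$W <- dequantize_array(p$W)
      p
    })
  }
  structure(list(spec = payload$spec, params = params, levels = payload$levels),
            class = "echo_model")
}
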