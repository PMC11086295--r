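# Neural-network engine: seeded initialisation, forward/backward passes
# and Adam updates over model_spec layer lists. Convolution, transposed
# convolution and pooling run in compiled code (src/conv_ops.cpp);
# everything else is vectorised R. Activations are stored as column-major
# arrays (H, W, C, N); flat activations as (N, features) matrices.

BN_EPS <- 1e-3
# moving-statistics momentum; 0.9 keeps inference statistics tracking the
# weights on datasets with only tens of batches per epoch
BN_MOMENTUM <- 0.9

#' Initialise model parameters for a specification
#'
#' He-normal initialisation for convolution and dense kernels
#' (`sd = sqrt(2 / fan_in)`), zero biases, unit-gain batch normalisation.
#' Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class `echo_model`.
#' @export
nn_init <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  in_shapes <- c(list(spec$input_shape), head(spec$shapes, -1L))
  params <- with_seed(seed, lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    s_in <- in_shapes[[i]]
    switch(l$kind,
      conv2d = , tconv2d = {
        fan_in <- prod(l$kernel) * s_in[3]
        list(W = array(rnorm(prod(l$kernel) * s_in[3] * l$filters, 0, sqrt(2 / fan_in)),
                       dim = c(l$kernel, s_in[3], l$filters)),
             b = numeric(l$filters))
      },
      dense = list(W = matrix(rnorm(s_in * l$units, 0, sqrt(2 / s_in)), s_in, l$units),
                   b = numeric(l$units)),
      batchnorm = {
        c <- tail(s_in, 1L)
        list(gamma = rep(1, c), beta = numeric(c),
             moving_mean = numeric(c), moving_var = rep(1, c))
      },
      NULL)
  }))
  structure(list(spec = spec, params = params, levels = NULL),
            class = "echo_model")
}

#' @export
print.echo_model <- function(x, ...) {
  counts <- count_parameters(x$spec)
  cat(sprintf("<echo_model> %s parameters (%s trainable)%s\n",
              format(counts$total, big.mark = ","),
              format(counts$trainable, big.mark = ","),
              if (!is.null(x$levels)) paste0(", classes: ", paste(x$levels, collapse = ", ")) else ""))
  invisible(x)
}

# ---- batch normalisation -------------------------------------------------

# 4-D activations run through fused compiled kernels; flat activations
# through vectorised R.
bn_forward <- function(x, p, training) {
  d <- dim(x)
  conv_mode <- !is.null(d) && length(d) == 4L
  if (conv_mode) {
    if (training) {
      mom <- channel_moments_cpp(x)
      mu <- mom$mean; v <- mom$var
    } else {
      mu <- p$moving_mean; v <- p$moving_var
    }
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- scale_shift_cpp(x, istd, -mu * istd)
    y <- scale_shift_cpp(xhat, p$gamma, p$beta)
    list(y = y, cache = list(xhat = xhat, istd = istd, mu = mu, v = v,
                             conv = TRUE, training = training))
  } else {
    if (training) {
      mu <- colMeans(x)
      v <- pmax(colMeans(x^2) - mu^2, 0)
    } else {
      mu <- p$moving_mean; v <- p$moving_var
    }
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(x, 2, mu, `-`), 2, istd, `*`)
    y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    list(y = y, cache = list(xhat = xhat, istd = istd, mu = mu, v = v,
                             conv = FALSE, training = training))
  }
}

bn_backward <- function(dy, p, cache) {
  xhat <- cache$xhat
  if (cache$conv) {
    d <- dim(dy)
    m <- d[1] * d[2] * d[4]
    red <- bn_reduce_cpp(dy, xhat)
    if (cache$training) {
      dx <- bn_dx_cpp(dy, xhat, red$sdy, red$sdyx, p$gamma * cache$istd, m)
    } else {
      dx <- scale_shift_cpp(dy, p$gamma * cache$istd, numeric(d[3]))
    }
    list(dx = dx, grads = list(gamma = red$sdyx, beta = red$sdy))
  } else {
    m <- nrow(dy)
    sum_dy <- colSums(dy)
    sum_dyx <- colSums(dy * xhat)
    if (cache$training) {
      t1 <- sweep(dy, 2, sum_dy / m, `-`) - sweep(xhat, 2, sum_dyx / m, `*`)
      dx <- sweep(t1, 2, p$gamma * cache$istd, `*`)
    } else {
      dx <- sweep(dy, 2, p$gamma * cache$istd, `*`)
    }
    list(dx = dx, grads = list(gamma = sum_dyx, beta = sum_dy))
  }
}

# ---- forward / backward --------------------------------------------------

# Forward pass to the logits (any trailing softmax layer is skipped; use
# nn_softmax() on the result for probabilities). Returns the activations
# cache needed by nn_backward and, in training mode, updated moving
# statistics for the batch-norm layers.
nn_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  caches <- vector("list", length(spec$layers))
  bn_updates <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    res <- switch(l$kind,
      conv2d = {
        y <- conv2d_forward_cpp(x, p$W, p$b, l$stride[1], l$stride[2])
        list(y = y, cache = list(x = x))
      },
      tconv2d = {
        y <- tconv2d_forward_cpp(x, p$W, p$b, l$stride[1], l$stride[2])
        list(y = y, cache = list(x = x))
      },
      dense = list(y = sweep(x %*% p$W, 2, p$b, `+`), cache = list(x = x)),
      batchnorm = {
        r <- bn_forward(x, p, training)
        if (training) {
          bn_updates[[as.character(i)]] <- list(
            moving_mean = BN_MOMENTUM * p$moving_mean + (1 - BN_MOMENTUM) * r$cache$mu,
            moving_var = BN_MOMENTUM * p$moving_var + (1 - BN_MOMENTUM) * r$cache$v)
        }
        r
      },
      relu = {
        y <- relu_forward_cpp(x)
        list(y = y, cache = list(y = y))
      },
      leaky_relu = list(y = leaky_relu_forward_cpp(x, l$alpha),
                        cache = list(x = x)),
      sigmoid = {
        y <- 1 / (1 + exp(-x))
        list(y = y, cache = list(y = y))
      },
      maxpool = {
        r <- maxpool_forward_cpp(x, l$pool[1], l$pool[2], l$stride[1], l$stride[2])
        list(y = r$y, cache = list(idx = r$idx, in_dim = dim(x)))
      },
      avgpool = {
        y <- avgpool_forward_cpp(x, l$pool[1], l$pool[2], l$stride[1], l$stride[2])
        list(y = y, cache = list(in_dim = dim(x), l = l))
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- (runif(length(x)) >= l$rate) / (1 - l$rate)
          dim(mask) <- dim(x)
          list(y = x * mask, cache = list(mask = mask))
        } else {
          list(y = x, cache = list(mask = NULL))
        }
      },
      spatial_dropout = {
        if (training && l$rate > 0) {
          d <- dim(x)
          keep <- (runif(d[3] * d[4]) >= l$rate) / (1 - l$rate)
          mask <- rep(keep, each = d[1] * d[2])
          dim(mask) <- d
          list(y = x * mask, cache = list(mask = mask))
        } else {
          list(y = x, cache = list(mask = NULL))
        }
      },
      flatten = {
        d <- dim(x)
        list(y = t(matrix(x, prod(d[1:3]), d[4])), cache = list(in_dim = d))
      },
      reshape = list(y = array(t(x), dim = c(l$shape, nrow(x))),
                     cache = list(n = nrow(x))),
      softmax = list(y = x, cache = NULL),  # handled at the loss
      stop_invalid("unknown layer kind '%s'", l$kind))
    x <- res$y
    caches[i] <- list(res$cache)  # keep NULL caches as placeholders
  }
  list(logits = x, caches = caches, bn_updates = bn_updates)
}

# Backward pass from a gradient at the logits. Returns per-layer gradients
# (parallel to model$params) and the gradient at the input.
nn_backward <- function(model, caches, dlogits) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  dy <- dlogits
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    cache <- caches[[i]]
    dy <- switch(l$kind,
      conv2d = {
        r <- conv2d_backward_cpp(cache$x, p$W, dy, l$stride[1], l$stride[2])
        grads[[i]] <- list(W = r$dw, b = r$db)
        r$dx
      },
      tconv2d = {
        r <- tconv2d_backward_cpp(cache$x, p$W, dy, l$stride[1], l$stride[2])
        grads[[i]] <- list(W = r$dw, b = r$db)
        r$dx
      },
      dense = {
        grads[[i]] <- list(W = crossprod(cache$x, dy), b = colSums(dy))
        dy %*% t(p$W)
      },
      batchnorm = {
        r <- bn_backward(dy, p, cache)
        grads[[i]] <- r$grads
        r$dx
      },
      relu = relu_backward_cpp(dy, cache$y),
      leaky_relu = leaky_relu_backward_cpp(dy, cache$x, l$alpha),
      sigmoid = dy * cache$y * (1 - cache$y),
      maxpool = maxpool_backward_cpp(dy, cache$idx, cache$in_dim[1], cache$in_dim[2]),
      avgpool = avgpool_backward_cpp(dy, cache$in_dim[1], cache$in_dim[2],
                                     l$pool[1], l$pool[2], l$stride[1], l$stride[2]),
      dropout = , spatial_dropout = if (is.null(cache$mask)) dy else dy * cache$mask,
      flatten = array(t(dy), dim = cache$in_dim),
      reshape = {
        d <- dim(dy)
        t(matrix(dy, prod(d[1:3]), d[4]))
      },
      softmax = dy,
      stop_invalid("unknown layer kind '%s'", l$kind))
  }
  list(grads = grads, dx = dy)
}

#' Recalibrate batch-normalisation statistics on a reference set
#'
#' Replaces the exponentially averaged batch-norm moving statistics with
#' exact channel moments measured over `images` (weighted across
#' batches). After short training runs the exponential average still
#' remembers its initialisation; recalibrating against the training set
#' makes inference-mode behaviour reflect the learned weights. This is
#' the usual "precise BN" post-processing step.
#'
#' @param model An `echo_model` containing batch-norm layers.
#' @param images Reference images, `H x W x C x N` (normally the training
#'   partition).
#' @param batch_size Forward-pass batch size.
#' @return The model with updated moving statistics.
#' @export
nn_recalibrate_bn <- function(model, images, batch_size = 32L) {
  n <- dim(images)[4]
  bn_layers <- which(vapply(model$spec$layers, function(l) l$kind == "batchnorm",
                            logical(1)))
  acc <- lapply(bn_layers, function(i) list(mean = 0, e2 = 0))
  names(acc) <- as.character(bn_layers)
  for (sl in batch_slices(n, batch_size)) {
    fw <- nn_forward(model, images[, , , sl, drop = FALSE], training = TRUE)
    wgt <- length(sl) / n
    for (i in bn_layers) {
      key <- as.character(i)
      cache <- fw$caches[[i]]
      acc[[key]]$mean <- acc[[key]]$mean + wgt * cache$mu
      acc[[key]]$e2 <- acc[[key]]$e2 + wgt * (cache$v + cache$mu^2)
    }
  }
  for (i in bn_layers) {
    key <- as.character(i)
    model$params[[i]]$moving_mean <- acc[[key]]$mean
    model$params[[i]]$moving_var <- pmax(acc[[key]]$e2 - acc[[key]]$mean^2, 0)
  }
  model
}

apply_bn_updates <- function(model, bn_updates) {
  for (nm in names(bn_updates)) {
    i <- as.integer(nm)
    model$params[[i]]$moving_mean <- bn_updates[[nm]]$moving_mean
    model$params[[i]]$moving_var <- bn_updates[[nm]]$moving_var
  }
  model
}

# ---- losses --------------------------------------------------------------

#' Row-wise softmax
#'
#' Numerically stable softmax over the columns of a logit matrix.
#'
#' @param logits `N x K` matrix.
#' @return `N x K` matrix of probabilities; rows sum to one.
#' @export
nn_softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# Sparse categorical cross-entropy; labels are 0-based class indices.
# Returns the mean loss and the gradient at the logits.
softmax_xent <- function(logits, labels0, weight = 1) {
  n <- nrow(logits)
  probs <- nn_softmax(logits)
  picked <- probs[cbind(seq_len(n), labels0 + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), labels0 + 1L)] <-
    dlogits[cbind(seq_len(n), labels0 + 1L)] - 1
  list(loss = loss, dlogits = dlogits * (weight / n))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) lapply(p, function(a) a * 0)),
       v = lapply(params, function(p) lapply(p, function(a) a * 0)),
       t = 0L)
}

# Trainable arrays only; batch-norm moving statistics are buffers.
trainable_names <- function(p) setdiff(names(p), c("moving_mean", "moving_var"))

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in intersect(trainable_names(params[[i]]), names(g))) {
      # moment buffers are advanced in place inside the fused kernel
      params[[i]][[nm]] <- adam_update_cpp(params[[i]][[nm]], g[[nm]],
                                           state$m[[i]][[nm]], state$v[[i]][[nm]],
                                           lr, beta1, beta2, eps, corr1, corr2)
    }
  }
  list(params = params, state = state)
}
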