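# Declarative layer specifications with closed-form shape propagation and
# parameter counting. The layer vocabulary covers the compact classifier
# and the GAN generator; "same" padding uses ceil-mode output sizes (the
# convention required to reproduce the reference shape table, e.g. a
# 85-wide map pooling to 43).

layer_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' Layer constructors
#'
#' Build individual layer specifications for [model_spec()]. Convolutions
#' and pooling use `"same"` (ceil-mode) padding by default; strides and
#' kernels are `(height, width)` pairs (a scalar is recycled).
#'
#' @param filters,units Output channels (convolutions) or units (dense).
#' @param kernel,pool Kernel / pooling window size.
#' @param stride Stride; pooling defaults to its window size.
#' @param padding `"same"` or `"valid"`.
#' @param rate Dropout rate in `[0, 1]`.
#' @param alpha Negative-side slope of the leaky ReLU.
#' @param shape Target shape for `layer_reshape()` (`(H, W, C)`).
#' @return A `layer_spec` object.
#' @name layers
NULL

pair <- function(x) if (length(x) == 1L) c(x, x) else x[1:2]

#' @rdname layers
#' @export
layer_conv2d <- function(filters, kernel, stride = 1L, padding = "same") {
  layer_spec("conv2d", filters = as.integer(filters), kernel = pair(as.integer(kernel)),
             stride = pair(as.integer(stride)), padding = match.arg(padding, c("same", "valid")))
}

#' @rdname layers
#' @export
layer_tconv2d <- function(filters, kernel, stride = 2L) {
  layer_spec("tconv2d", filters = as.integer(filters), kernel = pair(as.integer(kernel)),
             stride = pair(as.integer(stride)))
}

#' @rdname layers
#' @export
layer_batchnorm <- function() layer_spec("batchnorm")

#' @rdname layers
#' @export
layer_relu <- function() layer_spec("relu")

#' @rdname layers
#' @export
layer_leaky_relu <- function(alpha = 0.2) layer_spec("leaky_relu", alpha = alpha)

#' @rdname layers
#' @export
layer_sigmoid <- function() layer_spec("sigmoid")

#' @rdname layers
#' @export
layer_maxpool <- function(pool = 2L, stride = pool) {
  layer_spec("maxpool", pool = pair(as.integer(pool)), stride = pair(as.integer(stride)))
}

#' @rdname layers
#' @export
layer_avgpool <- function(pool = 2L, stride = pool) {
  layer_spec("avgpool", pool = pair(as.integer(pool)), stride = pair(as.integer(stride)))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  layer_spec("dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_spatial_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  layer_spec("spatial_dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_flatten <- function() layer_spec("flatten")

#' @rdname layers
#' @export
layer_reshape <- function(shape) layer_spec("reshape", shape = as.integer(shape))

#' @rdname layers
#' @export
layer_dense <- function(units) layer_spec("dense", units = as.integer(units))

#' @rdname layers
#' @export
layer_softmax <- function() layer_spec("softmax")

#' Assemble a model specification
#'
#' @param layers List of `layer_spec` objects, in order.
#' @param input_shape Input shape, `(H, W, C)` for image models or a
#'   single length for vector inputs (e.g. a latent code).
#' @param n_classes Number of classes for classifiers (`NULL` for
#'   generators).
#' @return An object of class `model_spec` with per-layer output shapes
#'   pre-computed.
#' @export
model_spec <- function(layers, input_shape, n_classes = NULL) {
  spec <- structure(list(layers = layers, input_shape = as.integer(input_shape),
                         n_classes = n_classes),
                    class = "model_spec")
  spec$shapes <- spec_shapes(spec)  # fails fast on inconsistent specs
  spec
}

same_out <- function(n, stride) as.integer(ceiling(n / stride))
valid_out <- function(n, k, stride) as.integer((n - k) %/% stride + 1L)

# Output shape of every layer; shapes[[l]] is the shape AFTER layer l.
spec_shapes <- function(spec) {
  shape <- spec$input_shape
  lapply(spec$layers, function(l) {
    shape <<- switch(l$kind,
      conv2d = {
        if (length(shape) != 3L) stop_invalid("conv2d needs a (H, W, C) input")
        if (l$padding == "same") {
          c(same_out(shape[1], l$stride[1]), same_out(shape[2], l$stride[2]), l$filters)
        } else {
          c(valid_out(shape[1], l$kernel[1], l$stride[1]),
            valid_out(shape[2], l$kernel[2], l$stride[2]), l$filters)
        }
      },
      tconv2d = c(shape[1] * l$stride[1], shape[2] * l$stride[2], l$filters),
      maxpool = ,
      avgpool = c(same_out(shape[1], l$stride[1]), same_out(shape[2], l$stride[2]), shape[3]),
      flatten = prod(shape),
      reshape = {
        if (prod(shape) != prod(l$shape)) {
          stop_invalid("reshape target %s incompatible with %s",
                       paste(l$shape, collapse = "x"), paste(shape, collapse = "x"))
        }
        l$shape
      },
      dense = {
        if (length(shape) != 1L) stop_invalid("dense needs a flat input")
        l$units
      },
      batchnorm = , relu = , leaky_relu = , sigmoid = ,
      dropout = , spatial_dropout = , softmax = shape,
      stop_invalid("unknown layer kind '%s'", l$kind))
    as.integer(shape)
  })
}

#' Count model parameters layer by layer
#'
#' Closed-form counts from the specification alone: a convolution with a
#' `kh x kw` kernel over `c_in` channels contributes
#' `kh*kw*c_in*filters + filters`, a dense layer `n_in*units + units`, and
#' batch normalisation `4*c` (of which the two moving statistics, `2*c`,
#' are not trainable). Activations, pooling, dropout, reshaping and
#' flattening carry no parameters.
#'
#' @param spec A [model_spec()].
#' @return List with `total`, `trainable` and `per_layer` (a data frame
#'   with the layer kind, output shape and parameter count).
#' @examples
#' counts <- count_parameters(build_classifier_spec())
#' counts$total      # 204256
#' counts$trainable  # 203648
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  in_shapes <- c(list(spec$input_shape), head(spec$shapes, -1L))
  rows <- lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    s_in <- in_shapes[[i]]
    s_out <- spec$shapes[[i]]
    params <- switch(l$kind,
      conv2d = , tconv2d = prod(l$kernel) * s_in[3] * l$filters + l$filters,
      dense = s_in * l$units + l$units,
      batchnorm = 4L * tail(s_in, 1L),
      0L)
    non_trainable <- if (l$kind == "batchnorm") 2L * tail(s_in, 1L) else 0L
    data.frame(layer = i, kind = l$kind,
               output_shape = paste(s_out, collapse = "x"),
               params = as.integer(params),
               non_trainable = as.integer(non_trainable))
  })
  per_layer <- do.call(rbind, rows)
  list(total = sum(per_layer$params),
       trainable = sum(per_layer$params) - sum(per_layer$non_trainable),
       per_layer = per_layer)
}

#' @export
print.model_spec <- function(x, ...) {
  counts <- count_parameters(x)
  cat(sprintf("<model_spec> input %s, %d layers, %s parameters (%s trainable)\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              format(counts$total, big.mark = ","),
              format(counts$trainable, big.mark = ",")))
  print(counts$per_layer[, c("kind", "output_shape", "params")], row.names = FALSE)
  invisible(x)
}
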