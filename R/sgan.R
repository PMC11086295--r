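# Semi-supervised GAN. The discriminator is the compact classifier
# backbone read out through two heads sharing every weight: C_out, an
# 8-way softmax over the class logits, and D_out, a real/fake score
# derived from the same logits as D = Z / (Z + 1) with Z the sum of
# exponentiated class logits (equivalently, a sigmoid of their
# log-sum-exp). A sample the classifier can confidently place in any
# class therefore scores as "real" without any additional parameters,
# which is the canonical shared-logit construction for semi-supervised
# GANs.

#' Semi-supervised GAN configuration
#'
#' @param latent_dim Dimensionality of the generator's latent input
#'   (standard normal).
#' @param labeled_fraction Fraction of the training partition whose labels
#'   are revealed to the supervised head (stratified per class).
#' @param batch_size Minibatch size for the real-image discriminator
#'   updates.
#' @param g_batch_size Minibatch size for the generated-image updates
#'   (the generator forward/backward passes dominate the compute, so this
#'   may be kept smaller than `batch_size`).
#' @param learning_rate Adam step size for both networks.
#' @param epochs Training epochs; per epoch and real batch the
#'   discriminator is updated twice (once on real, once on generated
#'   images) and the generator once — the 2:1 schedule.
#' @param unlabeled_real_feed If `TRUE` (default) the whole real training
#'   partition feeds the unsupervised head; if `FALSE` only the labelled
#'   subset does.
#' @param seed Integer seed.
#' @return An object of class `sgan_config`.
#' @export
sgan_config <- function(latent_dim = 100L, labeled_fraction = 1.0,
                        batch_size = 8L, g_batch_size = batch_size,
                        learning_rate = 0.003, epochs = 10L,
                        unlabeled_real_feed = TRUE, seed = 0L) {
  stopifnot(latent_dim >= 1, labeled_fraction > 0, labeled_fraction <= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 labeled_fraction = labeled_fraction,
                 batch_size = as.integer(batch_size),
                 g_batch_size = as.integer(g_batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 unlabeled_real_feed = unlabeled_real_feed,
                 seed = as.integer(seed)),
            class = "sgan_config")
}

#' Reference generator architecture
#'
#' Dense projection of the latent vector to `28 x 42 x 128`, two
#' stride-2 transposed convolutions (4 x 4 kernels) and a final 7 x 7
#' convolution down to 3 channels, with leaky-ReLU activations and a
#' sigmoid output mapping pixels into `[0, 1]`. Output shape
#' `112 x 168 x 3`; the discriminator input is narrowed to match (see
#' [crop_image_width()]).
#'
#' @param latent_dim Latent dimensionality (the reference value is 100).
#' @return A [model_spec()].
#' @examples
#' spec <- build_generator_spec()
#' count_parameters(spec)$per_layer
#' @export
build_generator_spec <- function(latent_dim = 100L) {
  model_spec(list(
    layer_dense(150528L),
    layer_leaky_relu(0.2),
    layer_reshape(c(28L, 42L, 128L)),
    layer_tconv2d(128L, kernel = 4L, stride = 2L),
    layer_leaky_relu(0.2),
    layer_tconv2d(128L, kernel = 4L, stride = 2L),
    layer_leaky_relu(0.2),
    layer_conv2d(3L, kernel = 7L, stride = 1L),
    layer_sigmoid()
  ), input_shape = as.integer(latent_dim))
}

#' Real/fake score from class logits
#'
#' `D = Z / (Z + 1)` with `Z = sum_k exp(logit_k)`, computed stably as a
#' sigmoid of the log-sum-exp. Strictly increasing in every logit and
#' bounded in (0, 1); with all logits at zero over 8 classes,
#' `D = 8/9`.
#'
#' @param logits Numeric vector of class logits, or a matrix with one row
#'   per sample.
#' @return Numeric vector of scores in (0, 1).
#' @export
d_out_activation <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  1 / (1 + exp(-lse))
}

#' Centre-crop images along the width axis
#'
#' The generator emits `112 x 168` images while the supervised pipeline
#' renders `112 x 170`; real images are centre-cropped to the common
#' width before feeding the discriminator.
#'
#' @param images Array `H x W x C x N` (or `H x W x C`).
#' @param width Target width.
#' @return Cropped array.
#' @export
crop_image_width <- function(images, width = 168L) {
  d <- dim(images)
  if (d[2] < width) stop_invalid("images narrower (%d) than the target width %d", d[2], width)
  off <- (d[2] - width) %/% 2L
  if (length(d) == 3L) images[, off + seq_len(width), , drop = FALSE]
  else images[, off + seq_len(width), , , drop = FALSE]
}

#' Dual-head discriminator readout
#'
#' Runs the shared backbone once and returns both readouts: class
#' probabilities (C_out) and the real/fake score (D_out).
#'
#' @param model A trained discriminator (`echo_model`).
#' @param images Array `112 x 168 x 3 x N`.
#' @return List with `c_out` (`N x n_classes` probabilities) and `d_out`
#'   (length-`N` scores in (0, 1)).
#' @export
discriminator_heads <- function(model, images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  fw <- nn_forward(model, images, training = FALSE)
  probs <- nn_softmax(fw$logits)
  if (!is.null(model$levels)) colnames(probs) <- model$levels
  list(c_out = probs, d_out = as.numeric(d_out_activation(fw$logits)))
}

# Stratified choice of the labelled subset.
pick_labeled <- function(y0, fraction) {
  labeled <- logical(length(y0))
  for (cl in unique(y0)) {
    idx <- which(y0 == cl)
    k <- max(1L, round_half_up(fraction * length(idx)))
    labeled[idx[seq_len(k)]] <- TRUE  # caller shuffles beforehand
  }
  labeled
}

#' Train the semi-supervised GAN
#'
#' Per epoch and real-data batch, three updates run: (1) the
#' discriminator on real images — sparse cross-entropy on the labelled
#' subset through C_out plus binary cross-entropy towards "real" through
#' D_out; (2) the discriminator on a freshly generated batch with D_out
#' target "fake"; (3) the generator through the frozen discriminator with
#' D_out target "real". Latent vectors are standard normal. SMOTE is
#' deliberately not applied here: the point of the semi-supervised run is
#' performance under scarce labels.
#'
#' @param images Real training images, `112 x W x 3 x N` (width 170
#'   images are centre-cropped to 168).
#' @param labels Class label per image; labels outside the revealed
#'   fraction are never used.
#' @param config An [sgan_config()].
#' @return List with `discriminator` and `generator` (`echo_model`s) and
#'   `history` (per-epoch mean losses: `d_real_class`, `d_real_adv`,
#'   `d_fake_adv`, `g_adv`).
#' @export
sgan_train <- function(images, labels, config = sgan_config()) {
  lab <- as_label0(labels)
  if (dim(images)[2] != 168L) images <- crop_image_width(images, 168L)
  n <- dim(images)[4]
  d_spec <- build_classifier_spec(input_shape = c(112L, 168L, 3L),
                                  n_classes = length(lab$levels))
  g_spec <- build_generator_spec(config$latent_dim)
  disc <- nn_init(d_spec, seed = config$seed)
  disc$levels <- lab$levels
  gen <- nn_init(g_spec, seed = config$seed + 1L)
  d_opt <- adam_init(disc$params)
  g_opt <- adam_init(gen$params)
  history <- NULL
  with_seed(config$seed + 2L, {
    perm <- sample.int(n)
    labeled <- pick_labeled(lab$y[perm], config$labeled_fraction)
    if (length(unique(lab$y[perm][labeled])) < length(lab$levels)) {
      warning("labelled fraction so small that a class has no labelled sample")
    }
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep <- c(d_real_class = 0, d_real_adv = 0, d_fake_adv = 0, g_adv = 0)
      n_lab_batches <- 0L
      slices <- batch_slices(n, config$batch_size)
      for (sl in slices) {
        idx <- perm[ord[sl]]
        is_lab <- labeled[ord[sl]]
        m <- length(idx)
        # (1) discriminator on real images
        xb <- images[, , , idx, drop = FALSE]
        if (!config$unlabeled_real_feed && !any(is_lab)) next
        fw <- nn_forward(disc, xb, training = TRUE)
        disc <- apply_bn_updates(disc, fw$bn_updates)
        d <- as.numeric(d_out_activation(fw$logits))
        probs <- nn_softmax(fw$logits)
        adv_rows <- if (config$unlabeled_real_feed) seq_len(m) else which(is_lab)
        dlogits <- probs * (d - 1) / length(adv_rows)
        dlogits[setdiff(seq_len(m), adv_rows), ] <- 0
        adv_loss <- mean(-log(pmax(d[adv_rows], 1e-12)))
        class_loss <- 0
        if (any(is_lab)) {
          lr_rows <- which(is_lab)
          ce <- softmax_xent(fw$logits[lr_rows, , drop = FALSE], lab$y[idx[lr_rows]])
          dlogits[lr_rows, ] <- dlogits[lr_rows, ] + ce$dlogits
          class_loss <- ce$loss
          n_lab_batches <- n_lab_batches + 1L
        }
        bw <- nn_backward(disc, fw$caches, dlogits)
        upd <- adam_step(disc$params, bw$grads, d_opt, config$learning_rate)
        disc$params <- upd$params; d_opt <- upd$state
        # (2) discriminator on generated images
        m <- config$g_batch_size
        z <- matrix(rnorm(m * config$latent_dim), m, config$latent_dim)
        g_fw <- nn_forward(gen, z, training = TRUE)
        fake <- g_fw$logits  # generator output (sigmoid applied in-spec)
        f_fw <- nn_forward(disc, fake, training = TRUE)
        disc <- apply_bn_updates(disc, f_fw$bn_updates)
        d_fake <- as.numeric(d_out_activation(f_fw$logits))
        dlogits_f <- nn_softmax(f_fw$logits) * d_fake / m
        bw <- nn_backward(disc, f_fw$caches, dlogits_f)
        upd <- adam_step(disc$params, bw$grads, d_opt, config$learning_rate)
        disc$params <- upd$params; d_opt <- upd$state
        # (3) generator through the frozen discriminator
        z <- matrix(rnorm(m * config$latent_dim), m, config$latent_dim)
        g_fw <- nn_forward(gen, z, training = TRUE)
        f_fw <- nn_forward(disc, g_fw$logits, training = TRUE)
        d_gen <- as.numeric(d_out_activation(f_fw$logits))
        dlogits_g <- nn_softmax(f_fw$logits) * (d_gen - 1) / m
        bw_d <- nn_backward(disc, f_fw$caches, dlogits_g)  # gradients discarded
        bw_g <- nn_backward(gen, g_fw$caches, bw_d$dx)
        upd <- adam_step(gen$params, bw_g$grads, g_opt, config$learning_rate)
        gen$params <- upd$params; g_opt <- upd$state
        ep <- ep + c(class_loss, adv_loss,
                     mean(-log(pmax(1 - d_fake, 1e-12))),
                     mean(-log(pmax(d_gen, 1e-12))))
      }
      k <- length(slices)
      history <- rbind(history, data.frame(
        epoch = epoch,
        d_real_class = ep[1] / max(n_lab_batches, 1L),
        d_real_adv = ep[2] / k, d_fake_adv = ep[3] / k, g_adv = ep[4] / k))
    }
  })
  # short adversarial runs leave the exponential BN averages behind the
  # weights; measure exact statistics over the real training images
  disc <- nn_recalibrate_bn(disc, images, batch_size = config$batch_size)
  list(discriminator = disc, generator = gen, history = history)
}

#' Sample images from a trained generator
#'
#' @param generator A generator `echo_model`.
#' @param n Number of images.
#' @param seed Integer seed for the standard-normal latents.
#' @return Array `112 x 168 x 3 x n`.
#' @export
generate_images <- function(generator, n = 1L, seed = 0L) {
  latent_dim <- generator$spec$input_shape
  z <- with_seed(seed, matrix(rnorm(n * latent_dim), n, latent_dim))
  nn_forward(generator, z, training = FALSE)$logits
}

#' Classification performance across labelled fractions
#'
#' Trains one SGAN per labelled fraction on identical data, split and
#' seeds, then evaluates the supervised head on the held-out test
#' partition. The expected qualitative pattern is a decline in accuracy
#' and F1 as fewer labels are revealed.
#'
#' @param images,labels Full image stack and labels.
#' @param split A [stratified_split()] shared by all runs.
#' @param fractions Labelled fractions to sweep, e.g. `c(1, 0.5, 0.25)`.
#' @param config Base [sgan_config()]; its `labeled_fraction` is
#'   overridden per run.
#' @param test_images,test_labels Optional dedicated evaluation set; by
#'   default the split's test partition is used. A larger dedicated set
#'   gives the reported accuracies finer granularity.
#' @return Data frame with one row per fraction: `fraction`, `accuracy`,
#'   `macro_f1`.
#' @export
labeled_fraction_experiment <- function(images, labels, split,
                                        fractions = c(1, 0.5, 0.25),
                                        config = sgan_config(),
                                        test_images = NULL,
                                        test_labels = NULL) {
  lab <- as_label0(labels)
  if (is.null(test_images)) {
    test_images <- images[, , , split$test_idx, drop = FALSE]
    test_labels <- labels[split$test_idx]
  }
  test_imgs <- crop_image_width(test_images, 168L)
  test_y <- as_label0(test_labels, levels = lab$levels)$y
  rows <- lapply(fractions, function(fr) {
    cfg <- config
    cfg$labeled_fraction <- fr
    fit <- sgan_train(images[, , , split$train_idx, drop = FALSE],
                      labels[split$train_idx], cfg)
    probs <- predict(fit$discriminator, test_imgs)
    pred0 <- max.col(probs, ties.method = "first") - 1L
    rep_ <- evaluate_predictions(test_y, pred0, probs, levels = lab$levels)
    data.frame(fraction = fr, accuracy = rep_$accuracy, macro_f1 = rep_$macro_f1)
  })
  do.call(rbind, rows)
}
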