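# Stratified partitioning and SMOTE oversampling.

#' Stratified train / validation / test split
#'
#' Splits sample indices so that every class contributes the same
#' fractions to each partition. Within each class the test allocation is
#' `round(test_frac * n)` (half up) and the validation allocation is
#' `round(val_frac_of_remainder * (n - n_test))`, drawn after a seeded
#' shuffle; this per-class rounding reproduces conventional stratified
#' count tables cell for cell. For very small classes the test partition
#' has priority, then validation; a class that cannot populate all three
#' partitions triggers a warning.
#'
#' @param labels Vector (factor, character or integer) of class labels,
#'   one per sample.
#' @param test_frac Fraction of each class assigned to the test set.
#' @param val_frac_of_remainder Fraction of the remaining (non-test)
#'   samples assigned to validation.
#' @param seed Integer seed making the shuffle reproducible.
#' @return An object of class `dataset_split`: list with `train_idx`,
#'   `val_idx`, `test_idx` (1-based indices), `per_class_counts` (a
#'   class x partition count matrix) and `seed`.
#' @examples
#' split <- stratified_split(rep(c("a", "b"), c(90, 10)), 0.1, 0.2, seed = 1)
#' split$per_class_counts
#' @export
stratified_split <- function(labels, test_frac = 0.10,
                             val_frac_of_remainder = 0.20, seed = 0L) {
  if (test_frac <= 0 || test_frac >= 1 || val_frac_of_remainder <= 0 ||
      val_frac_of_remainder >= 1) {
    stop_invalid("fractions must lie strictly between 0 and 1")
  }
  labels <- as.factor(labels)
  classes <- levels(labels)
  train_idx <- integer(0); val_idx <- integer(0); test_idx <- integer(0)
  counts <- matrix(0L, nrow = length(classes), ncol = 3,
                   dimnames = list(classes, c("train", "val", "test")))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n <- length(idx)
      if (n == 0L) next
      idx <- idx[sample.int(n)]
      n_test <- min(round_half_up(test_frac * n), n)
      n_test <- max(n_test, if (n >= 1L) 1L else 0L)  # test has priority
      n_val <- min(round_half_up(val_frac_of_remainder * (n - n_test)), n - n_test)
      n_train <- n - n_test - n_val
      if (n_train == 0L || n_val == 0L) {
        warning(sprintf("class '%s' (%d samples) cannot populate all partitions", cl, n))
      }
      test_idx <- c(test_idx, idx[seq_len(n_test)])
      if (n_val > 0L) val_idx <- c(val_idx, idx[n_test + seq_len(n_val)])
      if (n_train > 0L) train_idx <- c(train_idx, idx[n_test + n_val + seq_len(n_train)])
      counts[cl, ] <- c(n_train, n_val, n_test)
    }
  })
  structure(list(train_idx = sort(train_idx), val_idx = sort(val_idx),
                 test_idx = sort(test_idx), per_class_counts = counts,
                 seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d val / %d test\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx)))
  print(x$per_class_counts)
  invisible(x)
}

#' SMOTE oversampling to equalised class counts
#'
#' Synthetic minority oversampling: every class is raised to the size of
#' the largest class (or an explicit target) by interpolating between a
#' randomly chosen class member and one of its `k_neighbors` nearest
#' same-class neighbours, `x_new = x_i + u * (x_nn - x_i)` with
#' `u ~ U[0, 1)`. Original rows are preserved unchanged and synthetic rows
#' are appended. Apply this to the training partition only; validation and
#' test sets must keep their natural imbalance.
#'
#' Feature rows may be any numeric vectors; for image classifiers the
#' flattened input images are a valid choice since pixel intensities live
#' in the convex set `[0, 1]`.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Class label per row.
#' @param k_neighbors Number of nearest neighbours considered (reduced to
#'   `class size - 1` for tiny classes; a singleton class falls back to
#'   duplication with a warning).
#' @param target_count `"max"` (default: the largest class count) or an
#'   integer target for every class.
#' @param seed Integer seed.
#' @return List with `features` (original rows first, then synthetic) and
#'   `labels`.
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5L,
                             target_count = "max", seed = 0L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  target <- if (identical(target_count, "max")) max(counts) else as.integer(target_count)
  new_rows <- list(); new_labels <- character(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      n_c <- counts[[cl]]
      n_needed <- target - n_c
      if (n_needed <= 0L) next
      idx <- which(labels == cl)
      x_c <- features[idx, , drop = FALSE]
      if (n_c == 1L) {
        warning(sprintf("class '%s' has a single sample; duplicating it", cl))
        synth <- x_c[rep(1L, n_needed), , drop = FALSE]
      } else {
        k <- min(k_neighbors, n_c - 1L)
        # k nearest same-class neighbours via squared Euclidean distances
        sq <- rowSums(x_c^2)
        d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x_c)
        diag(d2) <- Inf
        ord_k <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
        nn <- if (k == 1L) matrix(ord_k, ncol = 1L) else t(ord_k)
        base <- sample.int(n_c, n_needed, replace = TRUE)
        pick <- nn[cbind(base, sample.int(k, n_needed, replace = TRUE))]
        u <- runif(n_needed)
        synth <- x_c[base, , drop = FALSE] +
          (x_c[pick, , drop = FALSE] - x_c[base, , drop = FALSE]) * u
      }
      new_rows[[cl]] <- synth
      new_labels <- c(new_labels, rep(cl, n_needed))
    }
  })
  if (length(new_rows)) {
    features <- rbind(features, do.call(rbind, new_rows))
    labels <- factor(c(as.character(labels), new_labels), levels = levels(labels))
  }
  list(features = features, labels = labels)
}

#' Flatten an image stack to a sample-by-feature matrix
#'
#' @param images Array `H x W x C x N`.
#' @return `N x (H*W*C)` matrix (row `i` is image `i`).
#' @export
flatten_images <- function(images) {
  d <- dim(images)
  t(matrix(images, prod(d[1:3]), d[4]))
}

#' Rebuild an image stack from a flattened matrix
#'
#' Inverse of [flatten_images()].
#'
#' @param mat `N x (H*W*C)` matrix.
#' @param shape Spatial shape `(H, W, C)`.
#' @return Array `H x W x C x N`.
#' @export
unflatten_images <- function(mat, shape = c(112L, 170L, 3L)) {
  array(t(mat), dim = c(shape, nrow(mat)))
}
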