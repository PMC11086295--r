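# Per-class metrics, confusion matrices and pairwise (one-vs-one)
# ROC/AUC evaluation.

label0 <- function(x, n_classes = NULL, levels = NULL) {
  if (is.factor(x) || is.character(x)) {
    f <- if (is.null(levels)) as.factor(x) else factor(x, levels = levels)
    y <- as.integer(f) - 1L
    lev <- levels(f)
  } else {
    y <- as.integer(x)
    lev <- levels
  }
  k <- if (!is.null(n_classes)) n_classes else if (!is.null(lev)) length(lev) else max(y) + 1L
  if (any(y < 0L | y >= k)) stop_invalid("labels must lie in [0, %d)", k)
  if (is.null(lev)) lev <- as.character(seq_len(k) - 1L)
  list(y = y, levels = lev, k = as.integer(k))
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`.
#' With `normalize = TRUE` each non-empty row is scaled to sum to one.
#'
#' @param y_true,y_pred True and predicted labels (factors, characters, or
#'   0-based integers).
#' @param n_classes Number of classes (inferred from factor levels or the
#'   label range when omitted).
#' @param normalize Row-normalise the counts.
#' @return `n_classes x n_classes` matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL, normalize = FALSE) {
  lt <- label0(y_true, n_classes)
  lp <- label0(y_pred, lt$k, levels = lt$levels)
  cm <- matrix(0, lt$k, lt$k, dimnames = list(true = lt$levels, pred = lt$levels))
  for (i in seq_along(lt$y)) {
    cm[lt$y[i] + 1L, lp$y[i] + 1L] <- cm[lt$y[i] + 1L, lp$y[i] + 1L] + 1
  }
  if (normalize) {
    rs <- rowSums(cm)
    cm <- cm / ifelse(rs == 0, 1, rs)
  }
  cm
}

#' Per-class precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * P * R / (P + R)` — the harmonic mean of precision and
#' recall. Any zero denominator yields a metric of 0 (the conservative
#' convention for classes never predicted or absent).
#'
#' @param confusion Square count matrix from [confusion_matrix()].
#' @return Data frame with one row per class: `class`, `precision`,
#'   `recall`, `f1`.
#' @export
precision_recall_f1 <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(confusion)) - 1L)
  data.frame(class = classes, precision = precision, recall = recall, f1 = f1,
             row.names = NULL)
}

#' Pairwise (one-vs-one) ROC AUC
#'
#' For each unordered class pair `(a, b)`, samples of those two classes
#' are retained and scored by the renormalised probability
#' `p_a / (p_a + p_b)`; the AUC is the Mann-Whitney rank statistic with
#' ties given half credit, i.e. the probability that a random class-`a`
#' sample outranks a random class-`b` sample. Pairs involving a class
#' with no samples are reported as `NA`.
#'
#' @param y_true True labels.
#' @param probs `N x n_classes` matrix of class probabilities.
#' @return Data frame with `class_a`, `class_b`, `auc`.
#' @export
pairwise_roc_auc <- function(y_true, probs) {
  lt <- label0(y_true, ncol(probs),
               levels = if (!is.null(colnames(probs))) colnames(probs))
  k <- lt$k
  rows <- list()
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      ia <- which(lt$y == a - 1L)
      ib <- which(lt$y == b - 1L)
      auc <- if (length(ia) == 0L || length(ib) == 0L) {
        NA_real_
      } else {
        pa <- probs[c(ia, ib), a]
        pb <- probs[c(ia, ib), b]
        denom <- pa + pb
        score <- ifelse(denom == 0, 0.5, pa / ifelse(denom == 0, 1, denom))
        r <- rank(score)  # average ranks give ties half credit
        na <- length(ia)
        (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * length(ib))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class_a = lt$levels[a], class_b = lt$levels[b], auc = auc)
    }
  }
  do.call(rbind, rows)
}

#' Assemble an evaluation report from predictions
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same coding).
#' @param probs Optional probability matrix enabling the pairwise AUC
#'   table.
#' @param levels Optional class names.
#' @return An object of class `eval_report`: per-class metrics, macro F1
#'   (unweighted mean of per-class F1), accuracy, raw and row-normalised
#'   confusion matrices, and pairwise AUCs.
#' @export
evaluate_predictions <- function(y_true, y_pred, probs = NULL, levels = NULL) {
  lt <- label0(y_true, if (!is.null(probs)) ncol(probs), levels = levels)
  lp <- label0(y_pred, lt$k, levels = lt$levels)
  cm <- confusion_matrix(lt$y, lp$y, lt$k)
  dimnames(cm) <- list(true = lt$levels, pred = lt$levels)
  per_class <- precision_recall_f1(cm)
  rs <- rowSums(cm)
  structure(list(
    per_class = per_class,
    macro_f1 = mean(per_class$f1),
    accuracy = sum(diag(cm)) / sum(cm),
    confusion = cm,
    normalized_confusion = cm / ifelse(rs == 0, 1, rs),
    pairwise_auc = if (!is.null(probs)) pairwise_roc_auc(lt$y, probs)
  ), class = "eval_report")
}

#' Evaluate a trained model on a labelled test set
#'
#' Runs the model on held-out images (which must be disjoint from the
#' training data for the metrics to mean anything) and assembles the full
#' report.
#'
#' @param model A trained `echo_model`.
#' @param images Test images `H x W x C x N`.
#' @param labels True labels.
#' @return An `eval_report`; see [evaluate_predictions()].
#' @export
evaluate_model <- function(model, images, labels) {
  if (length(dim(images)) != 4L || dim(images)[4] == 0L) {
    stop_invalid("a non-empty 4-D test image stack is required")
  }
  probs <- predict(model, images)
  pred0 <- max.col(probs, ties.method = "first") - 1L
  evaluate_predictions(labels, pred0, probs,
                       levels = if (!is.null(model$levels)) model$levels)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, macro F1 %.3f\n", x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Lossless round trip via [eval_report_from_json()].
#'
#' @param report An `eval_report`.
#' @return A JSON string.
#' @export
eval_report_json <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(
    per_class = report$per_class,
    macro_f1 = report$macro_f1,
    accuracy = report$accuracy,
    classes = rownames(report$confusion),
    confusion = unname(report$confusion),
    normalized_confusion = unname(report$normalized_confusion),
    pairwise_auc = report$pairwise_auc
  )
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
}

#' Rebuild an evaluation report from its JSON form
#'
#' @param json A string produced by [eval_report_json()].
#' @return An `eval_report`.
#' @export
eval_report_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  cm <- matrix(unlist(p$confusion), length(p$classes), byrow = FALSE)
  ncm <- matrix(unlist(p$normalized_confusion), length(p$classes), byrow = FALSE)
  dimnames(cm) <- dimnames(ncm) <- list(true = p$classes, pred = p$classes)
  structure(list(per_class = p$per_class, macro_f1 = p$macro_f1,
                 accuracy = p$accuracy, confusion = cm,
                 normalized_confusion = ncm,
                 pairwise_auc = p$pairwise_auc),
            class = "eval_report")
}
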