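test_that("confusion matrices count and normalise as expected", {
  cm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), 2L)
  expect_equal(unname(cm), matrix(c(1, 0, 1, 1), 2))
  ncm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), 2L, normalize = TRUE)
  expect_equal(unname(ncm), matrix(c(0.5, 0, 0.5, 1), 2))
  perfect <- confusion_matrix(0:3, 0:3, 4L)
  expect_equal(unname(perfect), diag(4))
  expect_error(confusion_matrix(c(0L, 5L), c(0L, 1L), 2L), "labels")
})

test_that("precision/recall/F1 follow the harmonic-mean identity", {
  cm <- matrix(c(1, 0, 1, 1), 2)
  prf <- precision_recall_f1(cm)
  expect_equal(prf$precision, c(1, 0.5))
  expect_equal(prf$recall, c(0.5, 1))
  expect_equal(prf$f1[1], 2 / 3)
  # degenerate rows/columns use the zero convention
  empty <- precision_recall_f1(matrix(c(2, 0, 0, 0), 2))
  expect_equal(empty$precision[2], 0)
  expect_equal(empty$recall[2], 0)
  expect_equal(empty$f1[2], 0)
})

test_that("F1 lies between min and mean of precision and recall", {
  set.seed(5)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 4), 3)
    prf <- precision_recall_f1(cm)
    ok <- prf$precision + prf$recall > 0
    expect_true(all(prf$f1[ok] >= pmin(prf$precision, prf$recall)[ok] - 1e-12))
    expect_true(all(prf$f1[ok] <= (prf$precision + prf$recall)[ok] / 2 + 1e-12))
  }
})

# brute-force O(n^2) AUC: concordant pairs + half credit for ties
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("pairwise AUC equals brute-force pair enumeration", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- 60
    y <- sample(0:2, n, replace = TRUE)
    probs <- matrix(runif(n * 3), n, 3)
    probs <- probs / rowSums(probs)
    probs[cbind(1:n, y + 1)] <- probs[cbind(1:n, y + 1)] + runif(n)  # informative
    probs <- probs / rowSums(probs)
    tab <- pairwise_roc_auc(y, probs)
    for (r in seq_len(nrow(tab))) {
      a <- as.integer(tab$class_a[r]); b <- as.integer(tab$class_b[r])
      sa <- probs[y == a, a + 1] / (probs[y == a, a + 1] + probs[y == a, b + 1])
      sb <- probs[y == b, a + 1] / (probs[y == b, a + 1] + probs[y == b, b + 1])
      expect_equal(tab$auc[r], brute_auc(sa, sb), tolerance = 1e-12)
    }
  }
})

test_that("pairwise AUC honours the tie and separation conventions", {
  y <- rep(0:1, each = 5)
  sep <- cbind(c(rep(0.9, 5), rep(0.1, 5)), c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(pairwise_roc_auc(y, sep)$auc, 1)
  tied <- matrix(0.5, 10, 2)
  expect_equal(pairwise_roc_auc(y, tied)$auc, 0.5)
})

test_that("rank-based AUC matches an established ROC implementation", {
  set.seed(13)
  y <- rep(0:1, each = 40)
  probs <- cbind(rnorm(80, ifelse(y == 0, 1, 0)), rnorm(80, y))
  probs <- exp(probs) / rowSums(exp(probs))
  ours <- pairwise_roc_auc(y, probs)$auc
  score <- probs[, 1] / (probs[, 1] + probs[, 2])
  ref <- as.numeric(pROC::auc(pROC::roc(y == 0, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("reports assemble coherent metrics and round-trip through JSON", {
  set.seed(4)
  y <- sample(0:2, 90, replace = TRUE)
  pred <- ifelse(runif(90) < 0.8, y, sample(0:2, 90, replace = TRUE))
  probs <- matrix(0.1, 90, 3)
  probs[cbind(1:90, pred + 1)] <- 0.8
  rep_ <- evaluate_predictions(y, pred, probs)
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion))
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1))
  rows <- rowSums(rep_$normalized_confusion)
  expect_equal(rows[rows > 0], rep(1, sum(rows > 0)), ignore_attr = TRUE)
  back <- eval_report_from_json(eval_report_json(rep_))
  expect_equal(back$accuracy, rep_$accuracy)
  expect_equal(back$confusion, rep_$confusion, ignore_attr = TRUE)
  expect_equal(back$pairwise_auc$auc, rep_$pairwise_auc$auc)
})

test_that("a majority-class predictor has recall 1 there and 0 elsewhere", {
  y <- rep(0:2, c(10, 5, 3))
  pred <- rep(0L, 18)
  prf <- precision_recall_f1(confusion_matrix(y, pred, 3L))
  expect_equal(prf$recall, c(1, 0, 0))
  expect_equal(prf$precision[1], 10 / 18)
})
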