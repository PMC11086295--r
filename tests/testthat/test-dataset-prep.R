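test_that("stratified split reproduces the survey allocation table", {
  labels <- rep(names(survey_class_totals), survey_class_totals)
  split <- stratified_split(labels, test_frac = 0.10,
                            val_frac_of_remainder = 0.20, seed = 1L)
  expect_equal(split$per_class_counts[names(survey_class_totals), ],
               survey_split_table)
})

test_that("small-class allocation follows test-then-validation priority", {
  split <- stratified_split(rep("a", 10), 0.1, 0.2, seed = 2L)
  expect_equal(unname(split$per_class_counts[1, ]), c(7L, 2L, 1L))
})

test_that("splits are deterministic, disjoint and exhaustive", {
  set.seed(33)
  for (rep_i in 1:5) {
    labels <- sample(letters[1:4], 120, replace = TRUE, prob = c(.5, .3, .15, .05))
    s1 <- stratified_split(labels, 0.15, 0.25, seed = rep_i)
    s2 <- stratified_split(labels, 0.15, 0.25, seed = rep_i)
    expect_identical(s1$train_idx, s2$train_idx)
    expect_identical(s1$val_idx, s2$val_idx)
    expect_identical(s1$test_idx, s2$test_idx)
    all_idx <- c(s1$train_idx, s1$val_idx, s1$test_idx)
    expect_equal(sort(all_idx), seq_along(labels))
    expect_equal(anyDuplicated(all_idx), 0L)
    # per-class fractions preserved within one sample
    for (cl in unique(labels)) {
      n <- sum(labels == cl)
      expect_lte(abs(sum(labels[s1$test_idx] == cl) - 0.15 * n), 1)
    }
  }
})

test_that("split counts are invariant under class relabelling", {
  labels <- rep(c("x", "y", "z"), c(40, 25, 12))
  s1 <- stratified_split(labels, 0.2, 0.2, seed = 4L)
  relabelled <- c(x = "z", y = "x", z = "y")[labels]
  s2 <- stratified_split(relabelled, 0.2, 0.2, seed = 4L)
  expect_equal(unname(s1$per_class_counts[c("x", "y", "z"), ]),
               unname(s2$per_class_counts[c("z", "x", "y"), ]))
})

test_that("SMOTE equalises counts while preserving originals", {
  set.seed(7)
  x <- rbind(matrix(rnorm(50 * 3), 50, 3), matrix(rnorm(12 * 3, 5), 12, 3))
  y <- rep(c("big", "small"), c(50, 12))
  out <- smote_oversample(x, y, k_neighbors = 5, seed = 1L)
  expect_equal(unname(table(out$labels)), c(50L, 50L), ignore_attr = TRUE)
  expect_equal(out$features[1:62, ], x, ignore_attr = TRUE)
})

test_that("already balanced input passes through SMOTE unchanged", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), each = 10)
  out <- smote_oversample(x, y, seed = 1L)
  expect_equal(out$features, x, ignore_attr = TRUE)
  expect_equal(as.character(out$labels), y)
})

test_that("two-point minority synthetics lie on the connecting segment", {
  x <- rbind(matrix(rnorm(30), 15, 2), c(0, 0), c(2, 4))
  y <- rep(c("maj", "min"), c(15, 2))
  out <- smote_oversample(x, y, k_neighbors = 1, seed = 3L)
  synth <- out$features[out$labels == "min", , drop = FALSE][-(1:2), , drop = FALSE]
  expect_equal(nrow(synth), 13L)
  # collinearity: every synthetic point is t * (2, 4), t in [0, 1)
  t_par <- synth[, 1] / 2
  expect_equal(synth[, 2], 4 * t_par, tolerance = 1e-12)
  expect_true(all(t_par >= 0 & t_par < 1))
})

test_that("SMOTE synthetics are convex combinations inside the class hull", {
  set.seed(11)
  x <- rbind(matrix(runif(60 * 4), 60, 4), matrix(runif(9 * 4, 2, 3), 9, 4))
  y <- rep(c("a", "b"), c(60, 9))
  out <- smote_oversample(x, y, seed = 5L)
  synth <- out$features[-seq_len(69), , drop = FALSE]
  cls_min <- apply(x[y == "b", ], 2, min)
  cls_max <- apply(x[y == "b", ], 2, max)
  expect_true(all(sweep(synth, 2, cls_min, `>=`)))
  expect_true(all(sweep(synth, 2, cls_max, `<=`)))
})

test_that("singleton classes fall back to duplication with a warning", {
  x <- rbind(matrix(rnorm(20), 10, 2), c(9, 9))
  y <- rep(c("a", "b"), c(10, 1))
  expect_warning(out <- smote_oversample(x, y, seed = 1L), "single sample")
  synth <- out$features[out$labels == "b", , drop = FALSE]
  expect_true(all(synth[, 1] == 9 & synth[, 2] == 9))
})

test_that("image flattening round-trips", {
  arr <- array(runif(4 * 5 * 3 * 6), c(4, 5, 3, 6))
  expect_equal(unflatten_images(flatten_images(arr), c(4L, 5L, 3L)), arr)
})
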