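# Architecture arithmetic, the compiled convolution against a naive R
# oracle, finite-difference gradient checks and export round trips.

naive_same_conv <- function(x, w, b, sh, sw) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  oh <- ceiling(H / sh); ow <- ceiling(W / sw)
  ph <- max((oh - 1) * sh + kh - H, 0) %/% 2
  pw <- max((ow - 1) * sw + kw - W, 0) %/% 2
  y <- array(0, c(oh, ow, cout, N))
  for (n in 1:N) for (co in 1:cout) for (oi in 1:oh) for (oj in 1:ow) {
    s <- b[co]
    for (di in 1:kh) for (dj in 1:kw) {
      i <- (oi - 1) * sh + di - ph
      j <- (oj - 1) * sw + dj - pw
      if (i >= 1 && i <= H && j >= 1 && j <= W) {
        s <- s + sum(x[i, j, , n] * w[di, dj, , co])
      }
    }
    y[oi, oj, co, n] <- s
  }
  y
}

test_that("classifier specification reproduces the reference shape table", {
  spec <- build_classifier_spec()
  shapes <- vapply(spec$shapes, paste, character(1), collapse = "x")
  expect_equal(shapes[1], "56x85x56")    # first convolution
  expect_equal(shapes[4], "28x43x56")    # ceil-mode pooling maps 85 -> 43
  expect_equal(shapes[21], "432")        # flatten = 2*3*72
  expect_equal(tail(shapes, 1), "8")
  counts <- count_parameters(spec)
  expect_equal(counts$total, 204256L)
  expect_equal(counts$trainable, 203648L)
  expect_equal(counts$total - counts$trainable, 2L * (56L + 72L + 56L + 72L + 48L))
})

test_that("parameter counting covers the trivial dense case", {
  spec <- model_spec(list(layer_dense(1L)), input_shape = 1L)
  expect_equal(count_parameters(spec)$total, 2L)
})

test_that("compiled convolution agrees with a naive R implementation", {
  set.seed(21)
  x <- array(rnorm(9 * 11 * 3 * 2), c(9, 11, 3, 2))
  w <- array(rnorm(3 * 5 * 3 * 4), c(3, 5, 3, 4))
  b <- rnorm(4)
  for (s in list(c(1L, 1L), c(2L, 2L))) {
    expect_equal(echoscope:::conv2d_forward_cpp(x, w, b, s[1], s[2]),
                 naive_same_conv(x, w, b, s[1], s[2]), tolerance = 1e-12)
  }
})

test_that("backpropagated gradients match finite differences everywhere", {
  tiny <- model_spec(list(
    layer_conv2d(3L, kernel = 3L, stride = 2L), layer_batchnorm(), layer_relu(),
    layer_maxpool(2L), layer_conv2d(4L, kernel = 3L), layer_batchnorm(),
    layer_leaky_relu(0.2), layer_avgpool(2L), layer_flatten(),
    layer_dense(5L), layer_batchnorm(), layer_relu(),
    layer_dense(3L), layer_softmax()
  ), input_shape = c(8L, 10L, 2L), n_classes = 3L)
  m <- nn_init(tiny, seed = 1L)
  set.seed(2)
  x <- array(rnorm(8 * 10 * 2 * 4), c(8, 10, 2, 4))
  y0 <- c(0L, 1L, 2L, 1L)
  loss_of <- function(mm) {
    fw <- echoscope:::nn_forward(mm, x, training = TRUE)
    echoscope:::softmax_xent(fw$logits, y0)$loss
  }
  fw <- echoscope:::nn_forward(m, x, training = TRUE)
  ls <- echoscope:::softmax_xent(fw$logits, y0)
  bw <- echoscope:::nn_backward(m, fw$caches, ls$dlogits)
  eps <- 1e-5
  for (li in seq_along(m$params)) {
    p <- m$params[[li]]
    if (is.null(p)) next
    for (nm in setdiff(names(p), c("moving_mean", "moving_var"))) {
      for (i in sample(length(p[[nm]]), min(4L, length(p[[nm]])))) {
        m1 <- m; m1$params[[li]][[nm]][i] <- p[[nm]][i] + eps
        m2 <- m; m2$params[[li]][[nm]][i] <- p[[nm]][i] - eps
        numeric_grad <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
        expect_lt(abs(bw$grads[[li]][[nm]][i] - numeric_grad), 1e-6)
      }
    }
  }
})

test_that("softmax outputs live on the simplex and are shift invariant", {
  set.seed(3)
  logits <- matrix(rnorm(12 * 8, sd = 4), 12, 8)
  p <- nn_softmax(logits)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 12), tolerance = 1e-12)
  shifted <- nn_softmax(logits + 100)
  expect_equal(max.col(shifted, ties.method = "first"), max.col(p, ties.method = "first"))
  expect_equal(shifted, p, tolerance = 1e-9)
})

test_that("untrained model predictions are valid probabilities", {
  m <- nn_init(build_classifier_spec(n_classes = 4L), seed = 5L)
  x <- array(runif(112 * 170 * 3 * 3), c(112, 170, 3, 3))
  probs <- predict(m, x)
  expect_equal(dim(probs), c(3L, 4L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_error(predict(m, array(0, c(10, 10, 3, 1))), "shaped")
})

test_that("weight initialisation is deterministic in the seed", {
  m1 <- nn_init(build_classifier_spec(n_classes = 4L), seed = 9L)
  m2 <- nn_init(build_classifier_spec(n_classes = 4L), seed = 9L)
  expect_identical(m1$params, m2$params)
  m3 <- nn_init(build_classifier_spec(n_classes = 4L), seed = 10L)
  expect_false(identical(m1$params, m3$params))
})

test_that("exported models round-trip exactly without quantisation", {
  m <- nn_init(build_classifier_spec(n_classes = 4L), seed = 7L)
  m$levels <- c("a", "b", "c", "d")
  x <- array(runif(112 * 170 * 3 * 2), c(112, 170, 3, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  report <- export_compact(m, path, quantize = FALSE)
  expect_gt(report$bytes_full, 0)
  back <- load_compact(path)
  expect_equal(predict(back, x), predict(m, x), tolerance = 0)
})

test_that("8-bit quantised export is smaller and predictions stay close", {
  m <- nn_init(build_classifier_spec(n_classes = 4L), seed = 8L)
  m$levels <- letters[1:4]
  x <- array(runif(112 * 170 * 3 * 4), c(112, 170, 3, 4))
  p_full <- withr::local_tempfile(fileext = ".rds")
  p_q <- withr::local_tempfile(fileext = ".rds")
  export_compact(m, p_full, quantize = FALSE)
  rep_q <- export_compact(m, p_q, quantize = TRUE)
  expect_lt(file.size(p_q), file.size(p_full))
  expect_lt(rep_q$ratio, 0.5)
  back <- load_compact(p_q)
  expect_lt(max(abs(predict(back, x) - predict(m, x))), 0.1)
})
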