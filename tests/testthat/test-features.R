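# Feature pipeline oracles: exact framing arithmetic, analytic FFT bins,
# closed-form window sums, filter-bank geometry and DCT identities.

test_that("rate relabelling keeps samples and scales apparent frequency", {
  x <- sin(2 * pi * 100e3 * (0:132299) / 384000)
  rl <- relabel_rate(x, 384000, 44100)
  expect_identical(rl$waveform, x)
  expect_equal(rl$fs, 44100)
  stft <- compute_stft(rl$waveform, feature_config())
  peak_hz <- stft$freq_axis[which.max(rowSums(stft$values))]
  expect_equal(peak_hz, 100e3 * 44100 / 384000, tolerance = 44100 / 2048)
  # no-op when the rates agree
  expect_identical(relabel_rate(x, 44100, 44100)$waveform, x)
  expect_error(relabel_rate(x, 22050, 44100), "fs_native")
})

test_that("segmentation produces exact fixed-length segments", {
  fs <- 1000
  expect_length(segment_audio(numeric(9 * fs), fs, 3), 3L)
  expect_length(segment_audio(numeric(10 * fs), fs, 3), 3L)  # floor(10/3)
  padded <- segment_audio(numeric(2 * fs), fs, 3, keep_partial = TRUE)
  expect_length(padded, 1L)
  expect_length(padded[[1]], 3 * fs)
  expect_equal(padded[[1]][(2 * fs + 1):(3 * fs)], numeric(fs))
  expect_identical(segment_audio(numeric(0), fs, 3), list())
})

test_that("STFT framing matches the closed-form frame count and overlap", {
  cfg <- feature_config()
  expect_equal(cfg$win, 1102L)   # 25 ms at 44.1 kHz
  expect_equal(cfg$hop, 441L)    # 10 ms
  expect_equal((cfg$win - cfg$hop) / cfg$fs_target, 0.015, tolerance = 1e-3)
  stft <- compute_stft(numeric(132300), cfg)
  expect_equal(ncol(stft$values), 298L)  # 1 + floor((132300 - 1102)/441)
  expect_true(all(stft$values == 0))
  expect_error(compute_stft(numeric(500), cfg), "shorter")
})

test_that("a pure tone lands in its analytic FFT bin in every frame", {
  cfg <- feature_config()
  x <- sin(2 * pi * 10e3 * (0:44099) / 44100)
  stft <- compute_stft(x, cfg)
  expect_true(all(stft$values >= 0))
  bins <- apply(stft$values, 2, which.max) - 1L
  expect_true(all(bins == round(10e3 * cfg$fft_size / 44100)))
})

test_that("constant input reproduces the squared Hann window sum at DC", {
  cfg <- feature_config()
  stft <- compute_stft(rep(1, 132300), cfg)
  hann_sum <- sum(0.5 * (1 - cos(2 * pi * (0:1101) / 1102)))
  expect_equal(stft$values[1, 1], hann_sum^2, tolerance = 1e-6)
})

test_that("mel filter bank geometry: 128 rows, sparse response to one bin", {
  cfg <- feature_config()
  stft <- compute_stft(numeric(132300), cfg)
  stft$values[400, ] <- 1  # a single active FFT bin
  msfb <- compute_msfb(stft, cfg)
  expect_equal(nrow(msfb$values), 128L)
  active <- which(msfb$values[, 1] > log(cfg$log_floor) + 1e-6)
  expect_lte(length(active), 2L)          # triangular filters overlap in pairs
  if (length(active) == 2L) expect_equal(diff(active), 1L)
  # zero power maps to the log floor everywhere
  zero_msfb <- compute_msfb(compute_stft(numeric(132300), cfg), cfg)
  expect_true(all(zero_msfb$values == log(cfg$log_floor)))
})

test_that("scaling the power spectrum shifts the MSFB by log k", {
  cfg <- feature_config()
  x <- sin(2 * pi * 5e3 * (0:132299) / 44100)
  stft <- compute_stft(x, cfg)
  msfb1 <- compute_msfb(stft, cfg)
  stft4 <- stft
  stft4$values <- stft$values * 4
  msfb4 <- compute_msfb(stft4, cfg)
  strong <- msfb1$values > log(1e-4)  # rows where the floor is negligible
  expect_equal(msfb4$values[strong], msfb1$values[strong] + log(4), tolerance = 1e-3)
})

test_that("MFCC is the orthonormal DCT-II of the mel spectrum", {
  cfg <- feature_config()
  const <- new_msfb <- compute_msfb(compute_stft(numeric(132300), cfg), cfg)
  const$values <- matrix(2.5, 128, 298)
  mfcc <- compute_mfcc(const, cfg)
  expect_equal(nrow(mfcc$values), 20L)
  expect_equal(mfcc$values[1, ], rep(2.5 * sqrt(128), 298), tolerance = 1e-9)
  expect_true(all(abs(mfcc$values[-1, ]) < 1e-9))
  # full-order DCT matrix is orthogonal: perfect reconstruction
  d_full <- echoscope:::dct_matrix(128L, 128L)
  expect_equal(crossprod(d_full), diag(128), tolerance = 1e-10)
  expect_error(compute_mfcc(compute_stft(numeric(132300), cfg), cfg), "MSFB")
})

test_that("rendered images have the contracted shape, range and colormap", {
  set.seed(1)
  m <- matrix(rnorm(128 * 298), 128, 298)
  img <- render_input_image(m)
  expect_equal(dim(img$values), c(112L, 170L, 3L))
  expect_true(all(img$values >= 0 & img$values <= 1))
  # constant input -> spatially constant image at the colormap midpoint
  flat <- render_input_image(matrix(3, 10, 10))$values
  expect_equal(max(abs(sweep(flat, 3, flat[1, 1, ]))), 0)
  lut <- viridis_lut()
  expect_equal(flat[1, 1, ], (lut[128, ] + lut[129, ]) / 2, tolerance = 1e-9)
})

test_that("pixel colours equal direct lookup of the normalised intensities", {
  ramp <- matrix(c(0, 1, 2, 3), 2, 2)
  img <- render_input_image(ramp, out_shape = c(2L, 2L, 3L))$values
  lut <- viridis_lut()
  lookup <- function(v) {
    pos <- v * 255
    lo <- min(floor(pos), 254)
    lut[lo + 1, ] * (1 - (pos - lo)) + lut[lo + 2, ] * (pos - lo)
  }
  norm <- (ramp - min(ramp)) / diff(range(ramp))
  norm <- norm[2:1, ]  # the renderer flips the frequency axis
  for (i in 1:2) for (j in 1:2) {
    expect_equal(img[i, j, ], lookup(norm[i, j]), tolerance = 1e-12)
  }
})

test_that("bilinear resize preserves constants and corner values", {
  m <- matrix(1:12, 3, 4)
  r <- echoscope:::bilinear_resize(m, 7, 9)
  expect_equal(dim(r), c(7L, 9L))
  expect_equal(r[1, 1], m[1, 1])
  expect_equal(r[7, 9], m[3, 4])
  expect_equal(echoscope:::bilinear_resize(matrix(5, 2, 2), 4, 6),
               matrix(5, 4, 6))
})

test_that("dataset featurization yields a labelled image stack", {
  imd <- tiny_image_stack()
  expect_equal(dim(imd$images)[1:3], c(112L, 170L, 3L))
  expect_equal(dim(imd$images)[4], length(imd$labels))
  expect_true(all(imd$images >= 0 & imd$images <= 1))
})
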