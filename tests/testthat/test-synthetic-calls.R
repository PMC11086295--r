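# Closed-form oracles: a linear chirp's spectrogram ridge must track its
# instantaneous frequency, and a pure tone must land in its analytic FFT bin.

test_that("FM sweep ridge follows the closed-form instantaneous frequency", {
  tpl <- call_template("chirp", "FM_sweep", 80e3, 40e3, 0.005, 0.05,
                       amplitude_envelope = "rect")
  fs <- 384000
  x <- synthesize_call(tpl, fs)
  expect_length(x, round(0.005 * fs))  # 1920 samples
  cfg <- feature_config(fs_target = fs, win_ms = 0.5, hop_ms = 0.25,
                        fft_size = 2048L)
  stft <- compute_stft(x, cfg)
  bin_hz <- fs / cfg$fft_size
  # ridge tolerance: one bin plus half the sweep traversed inside a window
  sweep_rate <- abs(tpl$f_end - tpl$f_start) / tpl$pulse_duration
  tol <- bin_hz + sweep_rate * (cfg$win / fs) / 2
  for (k in seq_along(stft$time_axis)) {
    f_expected <- tpl$f_start + (tpl$f_end - tpl$f_start) *
      stft$time_axis[k] / tpl$pulse_duration
    f_peak <- stft$freq_axis[which.max(stft$values[, k])]
    expect_lt(abs(f_peak - f_expected), tol)
  }
  # end frames sit near the band edges (peak may fall anywhere in the
  # sub-band a window covers, so the bound is one full in-window sweep)
  tol_edge <- bin_hz + sweep_rate * cfg$win / fs
  expect_lt(abs(stft$freq_axis[which.max(stft$values[, 1])] - 80e3), tol_edge)
  expect_lt(abs(stft$freq_axis[which.max(stft$values[, ncol(stft$values)])] - 40e3), tol_edge)
})

test_that("CF pulse concentrates in the analytic FFT bin", {
  tpl <- call_template("cf", "CF", 50e3, 50e3, 0.010, 0.05,
                       amplitude_envelope = "rect")
  fs <- 384000
  x <- synthesize_call(tpl, fs)
  n <- length(x)
  spec <- Mod(stats::fft(x))[1:(n %/% 2)]
  expect_equal(which.max(spec) - 1L, round(50e3 / (fs / n)))
})

test_that("zero-amplitude template yields an all-zero waveform", {
  tpl <- call_template("silent", "FM_sweep", 50e3, 30e3, 0.005, 0.05,
                       amplitude = 0)
  expect_equal(synthesize_call(tpl, 384000), rep(0, 1920))
})

test_that("harmonics above Nyquist are dropped, not aliased", {
  tpl <- call_template("h", "CF", 50e3, 50e3, 0.01, 0.05, harmonics = 4L,
                       amplitude_envelope = "rect")
  # at fs = 384 kHz harmonics 1..3 fit below 192 kHz, harmonic 4 (200 kHz) not
  x <- synthesize_call(tpl, 384000)
  n <- length(x)
  spec <- Mod(stats::fft(x))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * 384000 / n
  peak_150 <- max(spec[abs(freqs - 150e3) < 2e3])
  alias_bin <- max(spec[abs(freqs - (384e3 - 200e3)) < 2e3])
  expect_gt(peak_150, 10 * alias_bin)
})

test_that("pulse count equals floor(duration / inter-pulse interval)", {
  for (tpl in fast_templates()) {
    for (dur in c(0.11, 0.2, 0.33)) {
      spec <- recording_spec(tpl, dur, snr_db = Inf)
      rec <- synthesize_recording(spec)
      # noise-free output is exactly zero between pulses; dilate the
      # nonzero mask to bridge within-pulse zero crossings of the carrier
      nz <- as.numeric(abs(rec$waveform) > 0)
      d <- stats::filter(nz, rep(1, 33), sides = 2)
      d[is.na(d)] <- nz[is.na(d)]
      onsets <- sum(diff(c(FALSE, d > 0)) == 1)
      expect_equal(onsets, floor(dur / tpl$inter_pulse_interval + 1e-9))
    }
  }
})

test_that("noise level matches the requested SNR over pulse regions", {
  tpl <- fast_templates()[[1]]
  clean <- synthesize_recording(recording_spec(tpl, 0.4, snr_db = Inf))$waveform
  noisy <- synthesize_recording(recording_spec(tpl, 0.4, snr_db = 10, seed = 3L))$waveform
  noise <- noisy - clean
  mask <- abs(clean) > 1e-9
  snr_est <- 10 * log10(mean(clean[mask]^2) / mean(noise^2))
  expect_equal(snr_est, 10, tolerance = 0.5)
})

test_that("identical recording specs give identical waveforms, seeds only move the noise", {
  tpl <- fast_templates()[[2]]
  r1 <- synthesize_recording(recording_spec(tpl, 0.3, snr_db = 15, seed = 7L))
  r2 <- synthesize_recording(recording_spec(tpl, 0.3, snr_db = 15, seed = 7L))
  expect_identical(r1$waveform, r2$waveform)
  r3 <- synthesize_recording(recording_spec(tpl, 0.3, snr_db = 15, seed = 8L))
  expect_false(identical(r1$waveform, r3$waveform))
  clean <- synthesize_recording(recording_spec(tpl, 0.3, snr_db = Inf))$waveform
  # both noise residuals are zero-mean white realisations of equal power
  n1 <- r1$waveform - clean
  n3 <- r3$waveform - clean
  expect_equal(sd(n1), sd(n3), tolerance = 0.1)
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
})

test_that("a recording shorter than one pulse warns and is noise-only", {
  tpl <- call_template("long", "CF", 40e3, 40e3, 0.02, 0.05)
  expect_warning(rec <- synthesize_recording(recording_spec(tpl, 0.01, snr_db = 20)),
                 "noise-only")
  expect_length(rec$waveform, round(0.01 * 384000))
})

test_that("generate_dataset delivers the requested class counts and determinism", {
  tpls <- fast_templates()
  # sub-pulse segment lengths keep this cheap; the noise-only warning is expected
  ds <- suppressWarnings(
    generate_dataset(tpls, c(10L, 10L, 10L, 10L), segment_s = 0.05, seed = 5L))
  expect_length(ds$waveforms, 40L)
  expect_equal(unname(table(ds$labels)), rep(10L, 4), ignore_attr = TRUE)
  expect_length(ds$waveforms[[1]], round(0.05 * 44100))
  ds2 <- suppressWarnings(
    generate_dataset(tpls, c(10L, 10L, 10L, 10L), segment_s = 0.05, seed = 5L))
  expect_identical(ds$waveforms, ds2$waveforms)
  expect_error(generate_dataset(list(), integer(0)), "template")
})

test_that("skewed class counts reproduce the survey-scale imbalance", {
  tpls <- fast_templates()[1:2]
  ds <- suppressWarnings(
    generate_dataset(tpls, c(1666L, 30L), segment_s = 0.01, seed = 2L,
                     snr_db = Inf, band_jitter = 0))
  counts <- table(ds$labels)
  expect_equal(unname(counts), c(1666L, 30L), ignore_attr = TRUE)
  ratio <- max(counts) / min(counts)
  expect_gt(ratio, 50)  # "approximately 60 times" the smallest class
  expect_lt(ratio, 70)
})

test_that("datasets export to WAV byte-identically with a manifest", {
  ds <- suppressWarnings(
    generate_dataset(fast_templates()[1:2], c(2L, 2L), segment_s = 0.02, seed = 9L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset_wavs(ds, d1)
  write_dataset_wavs(ds, d2)
  manifest <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(file.path(d1, manifest$filename))))
  for (f in manifest$filename) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})
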