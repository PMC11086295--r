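# Audio -> model-input image pipeline: sample-rate relabelling,
# segmentation, STFT, mel-scaled filter banks (MSFB), MFCC, and rendering
# to the fixed 112 x 170 x 3 input image the classifier consumes.

#' Feature extraction configuration
#'
#' Parameters of the spectrogram pipeline. Defaults follow the reference
#' pipeline: 3-s segments at a nominal 44.1 kHz, a 25 ms Hann analysis
#' window with a 10 ms hop (hence 15 ms overlap), 128 mel filters, and 20
#' retained cepstral coefficients.
#'
#' @param fs_target Nominal pipeline rate in Hz after relabelling.
#' @param segment_s Segment length in seconds.
#' @param win_ms,hop_ms Analysis window and hop in milliseconds.
#' @param n_mels Number of triangular mel filters.
#' @param n_mfcc Number of cepstral coefficients retained by the DCT.
#' @param fft_size FFT length in samples (window is zero-padded up to it).
#' @param log_floor Additive floor before the log, keeping silent frames
#'   finite.
#' @param center If `TRUE`, frames are centred by half-window zero padding
#'   on both sides; the default is plain left-aligned framing with the
#'   exact frame-count formula `1 + floor((L - win) / hop)`.
#' @param min_rms Segments whose root-mean-square amplitude falls below
#'   this threshold are dropped by the batch converters (0 disables; a
#'   light automated stand-in for manual screening of empty segments).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(fs_target = 44100, segment_s = 3, win_ms = 25,
                           hop_ms = 10, n_mels = 128L, n_mfcc = 20L,
                           fft_size = 2048L, log_floor = 1e-10,
                           center = FALSE, min_rms = 0) {
  if (hop_ms >= win_ms) stop_invalid("hop_ms must be smaller than win_ms")
  if (n_mfcc > n_mels) stop_invalid("n_mfcc cannot exceed n_mels")
  win <- as.integer(round(win_ms * fs_target / 1000))
  if (fft_size < win) stop_invalid("fft_size must be at least the window length (%d)", win)
  structure(list(fs_target = fs_target, segment_s = segment_s,
                 win_ms = win_ms, hop_ms = hop_ms,
                 win = win, hop = as.integer(round(hop_ms * fs_target / 1000)),
                 n_mels = as.integer(n_mels), n_mfcc = as.integer(n_mfcc),
                 fft_size = as.integer(fft_size), log_floor = log_floor,
                 center = center, min_rms = min_rms),
            class = "feature_config")
}

new_spectrogram_tensor <- function(values, kind, freq_axis = NULL, time_axis = NULL) {
  structure(list(values = values, kind = kind,
                 freq_axis = freq_axis, time_axis = time_axis),
            class = "spectrogram_tensor")
}

#' @export
print.spectrogram_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectrogram_tensor> kind=%s, %s\n", x$kind,
              paste(d, collapse = " x ")))
  invisible(x)
}

#' Relabel the nominal sample rate of ultrasonic audio
#'
#' Reinterprets samples recorded at `fs_native` as if they had been
#' sampled at `fs_target`, leaving the sample values untouched. This is
#' time expansion, not resampling: a component at frequency `f` reads as
#' `f * fs_target / fs_native` afterwards, shifting ultrasonic call
#' patterns into the audible band while preserving their shape. An
#' anti-aliased resampler would instead low-pass the signal and destroy
#' all content above `fs_target / 2`, which is exactly what must not
#' happen here.
#'
#' @param waveform Numeric vector of samples.
#' @param fs_native Native rate in Hz.
#' @param fs_target New nominal rate in Hz; must not exceed `fs_native`.
#' @return List with unchanged `waveform` and `fs = fs_target`.
#' @export
relabel_rate <- function(waveform, fs_native, fs_target) {
  if (fs_native < fs_target) {
    stop_invalid("relabelling only lowers the nominal rate (fs_native >= fs_target)")
  }
  list(waveform = waveform, fs = fs_target)
}

#' Cut audio into fixed-length segments
#'
#' @param waveform Numeric vector of samples.
#' @param fs Sample rate in Hz.
#' @param segment_s Segment length in seconds.
#' @param keep_partial If `TRUE`, a trailing remainder is zero-padded into
#'   a final segment; otherwise it is discarded.
#' @return List of numeric vectors, each of exactly
#'   `round(segment_s * fs)` samples.
#' @export
segment_audio <- function(waveform, fs, segment_s = 3, keep_partial = FALSE) {
  assert_scalar_positive(fs, "fs")
  seg_len <- as.integer(round(segment_s * fs))
  n <- length(waveform)
  if (n == 0L) return(list())
  n_full <- n %/% seg_len
  segments <- lapply(seq_len(n_full), function(k) {
    waveform[((k - 1L) * seg_len + 1L):(k * seg_len)]
  })
  rem <- n - n_full * seg_len
  if (keep_partial && rem > 0L) {
    tail_seg <- c(waveform[(n_full * seg_len + 1L):n], numeric(seg_len - rem))
    segments[[n_full + 1L]] <- tail_seg
  }
  segments
}

# Periodic Hann window (the analysis convention used throughout).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Short-time Fourier transform (power spectrogram)
#'
#' Hann-windowed STFT of one segment. With the default left-aligned
#' framing the frame count is exactly `1 + floor((L - win) / hop)`; each
#' frame is zero-padded from the window length up to `fft_size` and only
#' the non-negative frequency bins are kept.
#'
#' @param segment Numeric vector, at least one window long.
#' @param config A [feature_config()].
#' @return A `spectrogram_tensor` of kind `"STFT"`: a
#'   `(fft_size/2 + 1) x n_frames` non-negative power matrix with bin
#'   frequencies in `freq_axis` (Hz) and frame centres in `time_axis` (s).
#' @export
compute_stft <- function(segment, config) {
  stopifnot(inherits(config, "feature_config"))
  win <- config$win
  hop <- config$hop
  nfft <- config$fft_size
  if (config$center) {
    pad <- win %/% 2L
    segment <- c(numeric(pad), segment, numeric(pad))
  }
  L <- length(segment)
  if (L < win) stop_invalid("segment (%d samples) shorter than the analysis window (%d)", L, win)
  n_frames <- 1L + (L - win) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  frames <- matrix(segment[idx], nrow = win) * hann_window(win)
  padded <- rbind(frames, matrix(0, nfft - win, n_frames))
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  new_spectrogram_tensor(
    power, "STFT",
    freq_axis = (0:(nfft %/% 2L)) * config$fs_target / nfft,
    time_axis = (starts + (win - 1) / 2) / config$fs_target
  )
}

# Mel scale (Slaney convention): linear below 1 kHz, logarithmic above.
hz_to_mel <- function(f) {
  ifelse(f < 1000, 3 * f / 200, 15 + 27 * log(f / 1000) / log(6.4))
}
mel_to_hz <- function(m) {
  ifelse(m < 15, 200 * m / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

#' Triangular mel filter bank matrix
#'
#' Slaney-style bank: `n_mels` triangular filters with centres equally
#' spaced on the mel scale between `fmin` and `fmax`, area-normalised by
#' `2 / (f_upper - f_lower)`.
#'
#' @param n_mels Number of filters.
#' @param fft_size FFT length.
#' @param fs Sample rate in Hz.
#' @param fmin,fmax Frequency range covered by the bank.
#' @return A `n_mels x (fft_size/2 + 1)` weight matrix.
#' @export
mel_filterbank <- function(n_mels, fft_size, fs, fmin = 0, fmax = fs / 2) {
  n_bins <- fft_size %/% 2L + 1L
  if (n_mels > n_bins) stop_invalid("n_mels (%d) exceeds the number of FFT bins (%d)", n_mels, n_bins)
  fft_freqs <- (0:(n_bins - 1L)) * fs / fft_size
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  f_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lower <- (fft_freqs - f_pts[m]) / (f_pts[m + 1L] - f_pts[m])
    upper <- (f_pts[m + 2L] - fft_freqs) / (f_pts[m + 2L] - f_pts[m + 1L])
    fb[m, ] <- pmax(0, pmin(lower, upper)) * 2 / (f_pts[m + 2L] - f_pts[m])
  }
  fb
}

#' Mel-scaled filter bank features (MSFB)
#'
#' Applies the triangular mel filter bank to an STFT power spectrogram and
#' takes the natural log (with an additive floor so silent frames stay
#' finite).
#'
#' @param stft_power A `spectrogram_tensor` of kind `"STFT"`.
#' @param config A [feature_config()].
#' @return A `spectrogram_tensor` of kind `"MSFB"` with `n_mels` rows.
#' @export
compute_msfb <- function(stft_power, config) {
  stopifnot(inherits(stft_power, "spectrogram_tensor"))
  if (stft_power$kind != "STFT") stop_invalid("compute_msfb expects an STFT tensor")
  fb <- mel_filterbank(config$n_mels, config$fft_size, config$fs_target)
  values <- log(fb %*% stft_power$values + config$log_floor)
  new_spectrogram_tensor(values, "MSFB",
                         freq_axis = seq_len(config$n_mels),
                         time_axis = stft_power$time_axis)
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  n <- 0:(n_in - 1L)
  d <- sqrt(2 / n_in) * cos(pi * outer(k, n + 0.5) / n_in)
  d[1, ] <- sqrt(1 / n_in)
  d
}

#' Mel-frequency cepstral coefficients (MFCC)
#'
#' Orthonormal type-II discrete cosine transform along the mel axis of an
#' MSFB tensor, retaining the first `n_mfcc` coefficients.
#'
#' @param msfb A `spectrogram_tensor` of kind `"MSFB"`.
#' @param config A [feature_config()].
#' @return A `spectrogram_tensor` of kind `"MFCC"` with `n_mfcc` rows.
#' @export
compute_mfcc <- function(msfb, config) {
  stopifnot(inherits(msfb, "spectrogram_tensor"))
  if (msfb$kind != "MSFB") stop_invalid("compute_mfcc expects an MSFB tensor")
  d <- dct_matrix(config$n_mfcc, config$n_mels)
  new_spectrogram_tensor(d %*% msfb$values, "MFCC",
                         freq_axis = seq_len(config$n_mfcc),
                         time_axis = msfb$time_axis)
}

# Bilinear resize with corner-aligned sampling; constant-preserving.
bilinear_resize <- function(m, out_h, out_w) {
  interp_rows <- function(mat, n_out) {
    n_in <- nrow(mat)
    if (n_in == 1L) return(mat[rep(1L, n_out), , drop = FALSE])
    pos <- seq(0, n_in - 1L, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2L)
    fr <- pos - lo
    mat[lo + 1L, , drop = FALSE] * (1 - fr) + mat[lo + 2L, , drop = FALSE] * fr
  }
  t(interp_rows(t(interp_rows(m, out_h)), out_w))
}

#' Perceptually uniform colour lookup table
#'
#' 256-entry viridis lookup table (rows = RGB in `[0, 1]`) used to render
#' feature matrices as 3-channel images.
#'
#' @return A `256 x 3` numeric matrix.
#' @export
viridis_lut <- function() {
  unname(t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")))) / 255
}

#' Render a feature matrix as the fixed-size model input image
#'
#' Min-max normalises the matrix to `[0, 1]`, resizes it bilinearly to the
#' target spatial size, flips the frequency axis so low frequencies sit at
#' the bottom of the image, and maps intensities through a colour lookup
#' table to produce 3 channels. A constant (degenerate) input renders as
#' the colormap midpoint everywhere.
#'
#' @param feature A `spectrogram_tensor` (any 2-D kind) or plain matrix
#'   with frequency along rows and time along columns.
#' @param colormap A `K x 3` lookup table with values in `[0, 1]`;
#'   defaults to [viridis_lut()].
#' @param out_shape Output dimensions `(height, width, channels)`;
#'   channels must equal 3.
#' @return A `spectrogram_tensor` of kind `"image"` whose `values` are an
#'   array of the requested shape with entries in `[0, 1]`.
#' @export
render_input_image <- function(feature, colormap = viridis_lut(),
                               out_shape = c(112L, 170L, 3L)) {
  v <- if (inherits(feature, "spectrogram_tensor")) feature$values else feature
  if (!is.matrix(v)) stop_invalid("render_input_image expects a 2-D feature matrix")
  if (length(out_shape) != 3L || out_shape[3] != 3L) {
    stop_invalid("out_shape must be (height, width, 3)")
  }
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    v <- matrix(0.5, nrow(v), ncol(v))  # degenerate input -> colormap midpoint
  }
  g <- bilinear_resize(v, out_shape[1], out_shape[2])
  g <- g[rev(seq_len(nrow(g))), , drop = FALSE]  # low frequencies at the bottom
  k <- nrow(colormap)
  pos <- pmin(pmax(g, 0), 1) * (k - 1L)
  lo <- pmin(floor(pos), k - 2L)
  fr <- pos - lo
  img <- array(0, dim = out_shape)
  for (ch in 1:3) {
    img[, , ch] <- colormap[lo + 1L, ch] * (1 - fr) + colormap[lo + 2L, ch] * fr
  }
  new_spectrogram_tensor(img, "image")
}

#' Convert one segment to a model input image
#'
#' Runs the fixed pipeline STFT -> MSFB (-> MFCC) -> image on a single
#' segment already at the pipeline rate.
#'
#' @param segment Numeric vector of `round(segment_s * fs_target)` samples.
#' @param config A [feature_config()].
#' @param representation Feature fed to the image renderer: `"msfb"`
#'   (default, the best-performing representation), `"stft"` or `"mfcc"`.
#' @return An array of shape `112 x 170 x 3`.
#' @export
featurize_segment <- function(segment, config = feature_config(),
                              representation = c("msfb", "stft", "mfcc")) {
  representation <- match.arg(representation)
  stft <- compute_stft(segment, config)
  feat <- switch(representation,
                 stft = stft,
                 msfb = compute_msfb(stft, config),
                 mfcc = compute_mfcc(compute_msfb(stft, config), config))
  render_input_image(feat)$values
}

#' Convert a synthetic dataset to a stack of model input images
#'
#' Relabels each native-rate segment to the pipeline rate and featurizes
#' it. Segments produced by [generate_dataset()] are exactly one pipeline
#' segment long by construction.
#'
#' @param dataset An `echo_dataset` from [generate_dataset()].
#' @param config A [feature_config()].
#' @param representation See [featurize_segment()].
#' @return List with `images` (array `112 x 170 x 3 x N`) and `labels`
#'   (factor of length `N`).
#' @export
dataset_to_images <- function(dataset, config = feature_config(),
                              representation = "msfb") {
  stopifnot(inherits(dataset, "echo_dataset"))
  n <- length(dataset$waveforms)
  images <- array(0, dim = c(112L, 170L, 3L, n))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    rl <- relabel_rate(dataset$waveforms[[i]], dataset$fs_native, config$fs_target)
    if (config$min_rms > 0 && sqrt(mean(rl$waveform^2)) < config$min_rms) {
      keep[i] <- FALSE
      next
    }
    images[, , , i] <- featurize_segment(rl$waveform, config, representation)
  }
  list(images = images[, , , keep, drop = FALSE], labels = dataset$labels[keep])
}
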