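# Synthetic echolocation calls.
#
# Field recordings of the eight target species are restricted, so the
# package ships a parametric generator that emulates the statistical
# structure the classifier relies on: species-specific frequency-modulated
# (FM), constant-frequency (CF) or mixed FM-CF ultrasonic pulse trains,
# repeated at a species-typical interval, in additive white Gaussian
# noise at a configurable signal-to-noise ratio.

#' Describe one species' synthetic echolocation pulse
#'
#' A call template is a parametric description of a single pulse: the kind
#' of frequency modulation, the sweep band, duration, repetition interval,
#' harmonic content and amplitude envelope. Templates are fixture
#' constants: they reproduce the qualitative call-shape differences that
#' distinguish species in spectrograms, not measured parameters of real
#' bats.
#'
#' @param species_name Label attached to segments generated from this
#'   template.
#' @param call_kind One of `"FM_sweep"` (linear downward/upward chirp),
#'   `"CF"` (constant frequency), `"FM_CF"` (initial sweep settling into a
#'   constant tail).
#' @param f_start,f_end Sweep band edges in Hz at the native rate. For
#'   `"CF"` the pulse stays at `f_start`.
#' @param pulse_duration Pulse length in seconds.
#' @param inter_pulse_interval Onset-to-onset spacing in seconds; must
#'   exceed `pulse_duration`.
#' @param harmonics Number of harmonic components (fundamental included);
#'   harmonics that would cross the Nyquist frequency are dropped at
#'   synthesis time.
#' @param amplitude_envelope `"rect"` or `"hann"`.
#' @param amplitude Peak amplitude in `[0, 1]`.
#' @return An object of class `call_template`.
#' @examples
#' tpl <- call_template("demo", "FM_sweep", 8e4, 4e4, 0.005, 0.05)
#' wave <- synthesize_call(tpl, fs = 384000)
#' @export
call_template <- function(species_name, call_kind = c("FM_sweep", "CF", "FM_CF"),
                          f_start, f_end = f_start, pulse_duration,
                          inter_pulse_interval, harmonics = 1L,
                          amplitude_envelope = c("hann", "rect"),
                          amplitude = 0.9) {
  call_kind <- match.arg(call_kind)
  amplitude_envelope <- match.arg(amplitude_envelope)
  assert_scalar_positive(f_start, "f_start")
  assert_scalar_positive(f_end, "f_end")
  assert_scalar_positive(pulse_duration, "pulse_duration")
  assert_scalar_positive(inter_pulse_interval, "inter_pulse_interval")
  if (pulse_duration >= inter_pulse_interval) {
    stop_invalid("pulse_duration must be smaller than inter_pulse_interval")
  }
  if (harmonics < 1) stop_invalid("harmonics must be >= 1")
  if (amplitude < 0 || amplitude > 1) stop_invalid("amplitude must be in [0, 1]")
  structure(
    list(species_name = as.character(species_name), call_kind = call_kind,
         f_start = f_start, f_end = f_end, pulse_duration = pulse_duration,
         inter_pulse_interval = inter_pulse_interval,
         harmonics = as.integer(harmonics),
         amplitude_envelope = amplitude_envelope, amplitude = amplitude),
    class = "call_template"
  )
}

#' @export
print.call_template <- function(x, ...) {
  cat(sprintf("<call_template> %s: %s %.1f -> %.1f kHz, %.1f ms pulse every %.0f ms, %d harmonic(s)\n",
              x$species_name, x$call_kind, x$f_start / 1e3, x$f_end / 1e3,
              x$pulse_duration * 1e3, x$inter_pulse_interval * 1e3, x$harmonics))
  invisible(x)
}

#' Default call templates for the eight target species
#'
#' One template per species, in descending order of how common the species
#' is in the emulated survey (the same order used for species codes
#' elsewhere in the package). Sweep bands span roughly 20-150 kHz with
#' distinct, partially overlapping bands and a mix of FM, CF and FM-CF
#' shapes. The parameter values are synthetic fixture constants chosen to
#' give the classifier separable but non-trivial classes; they are not
#' acoustic measurements of the named species.
#'
#' @return Named list of eight [call_template()] objects.
#' @export
bat_call_templates <- function() {
  tpl <- list(
    call_template("R_muscatellum", "FM_CF",    40e3,  33e3, 0.008, 0.060),
    call_template("T_perforatus",  "FM_sweep", 30e3,  24e3, 0.006, 0.070, harmonics = 2L),
    call_template("P_kuhli",       "FM_sweep", 75e3,  40e3, 0.005, 0.065),
    call_template("R_nasutus",     "FM_sweep", 55e3,  38e3, 0.004, 0.055),
    call_template("E_bottae",      "FM_sweep", 48e3,  27e3, 0.006, 0.075),
    call_template("R_aegyptius",   "FM_sweep", 60e3,  20e3, 0.002, 0.050, harmonics = 3L),
    call_template("M_emarginatus", "FM_sweep", 120e3, 45e3, 0.003, 0.060),
    call_template("A_tridens",     "CF",       118e3, 118e3, 0.007, 0.080)
  )
  names(tpl) <- vapply(tpl, function(t) t$species_name, character(1))
  tpl
}

# Instantaneous frequency trajectory over one pulse (Hz per sample).
pulse_frequency <- function(template, n) {
  u <- if (n > 1) seq(0, 1, length.out = n) else 0
  switch(template$call_kind,
    FM_sweep = template$f_start + (template$f_end - template$f_start) * u,
    CF = rep(template$f_start, n),
    FM_CF = {
      # sweep over the first 40% of the pulse, constant tail at f_end
      knee <- 0.4
      f <- ifelse(u < knee,
                  template$f_start + (template$f_end - template$f_start) * u / knee,
                  template$f_end)
      f
    })
}

#' Synthesize one echolocation pulse
#'
#' Generates a single pulse waveform from a template. The instantaneous
#' frequency follows the template trajectory (linear in time for
#' `FM_sweep`); harmonics are added at integer multiples of the
#' fundamental with `1/h` amplitude weighting, and any harmonic whose
#' trajectory would cross the Nyquist frequency `fs/2` is dropped rather
#' than aliased. The output is fully determined by the template and `fs`.
#'
#' @param template A [call_template()].
#' @param fs Sample rate in Hz.
#' @param seed Accepted for interface symmetry with the stochastic
#'   generators; pulse synthesis is deterministic.
#' @return Numeric vector of `round(pulse_duration * fs)` samples in
#'   `[-1, 1]`.
#' @export
synthesize_call <- function(template, fs, seed = NULL) {
  stopifnot(inherits(template, "call_template"))
  assert_scalar_positive(fs, "fs")
  n <- as.integer(round(template$pulse_duration * fs))
  if (n <= 0) stop_invalid("pulse_duration too short for sample rate %g", fs)
  f <- pulse_frequency(template, n)
  phase <- 2 * pi * cumsum(f) / fs
  x <- numeric(n)
  for (h in seq_len(template$harmonics)) {
    if (max(f) * h >= fs / 2) next  # would alias: clip this harmonic
    x <- x + sin(h * phase) / h
  }
  env <- switch(template$amplitude_envelope,
                rect = rep(1, n),
                hann = 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n))))
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- x * (template$amplitude / peak)
  x
}

#' Parameters of one synthetic recording
#'
#' @param template A [call_template()].
#' @param duration Recording length in seconds (at the native rate).
#' @param snr_db Signal-to-noise ratio in dB measured over pulse regions;
#'   `Inf` disables noise.
#' @param fs_native Native sample rate in Hz (default 384 kHz, the rate of
#'   the ultrasound microphone class this generator emulates).
#' @param seed Integer seed controlling the noise realisation.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(template, duration, snr_db = 20,
                           fs_native = 384000, seed = 0L) {
  stopifnot(inherits(template, "call_template"))
  assert_scalar_positive(duration, "duration")
  assert_scalar_positive(fs_native, "fs_native")
  if (fs_native <= 2 * max(template$f_start, template$f_end)) {
    stop_invalid("fs_native must exceed twice the maximum call frequency")
  }
  structure(list(template = template, duration = duration, snr_db = snr_db,
                 fs_native = fs_native, seed = seed),
            class = "recording_spec")
}

#' Synthesize a recording: a pulse train in noise
#'
#' Places pulses every `inter_pulse_interval` seconds starting at
#' `onset_offset`, then adds white Gaussian noise scaled so that
#' `10*log10(P_signal / P_noise) = snr_db`, with the signal power measured
#' over the pulse regions. Identical specs (including the seed) produce
#' identical waveforms.
#'
#' @param spec A [recording_spec()].
#' @param onset_offset Shift of the first pulse onset in seconds (used by
#'   [generate_dataset()] to randomise pulse phase across segments).
#' @return List with `waveform` (numeric vector) and `fs` (native rate).
#' @export
synthesize_recording <- function(spec, onset_offset = 0) {
  stopifnot(inherits(spec, "recording_spec"))
  tpl <- spec$template
  fs <- spec$fs_native
  n <- as.integer(round(spec$duration * fs))
  pulse <- synthesize_call(tpl, fs)
  n_pulses <- floor(spec$duration / tpl$inter_pulse_interval + 1e-9)
  x <- numeric(n)
  signal_mask <- logical(n)
  if (n_pulses < 1L || length(pulse) > n) {
    warning("recording shorter than one pulse; emitting noise-only output")
    n_pulses <- 0L
  }
  for (k in seq_len(n_pulses) - 1L) {
    start <- as.integer(round((onset_offset + k * tpl$inter_pulse_interval) * fs)) + 1L
    if (start > n) break
    idx <- start:min(start + length(pulse) - 1L, n)
    x[idx] <- x[idx] + pulse[seq_along(idx)]
    signal_mask[idx] <- TRUE
  }
  if (is.finite(spec$snr_db)) {
    p_signal <- if (any(signal_mask)) mean(x[signal_mask]^2) else tpl$amplitude^2 / 2
    sd_noise <- sqrt(p_signal / 10^(spec$snr_db / 10))
    noise <- with_seed(spec$seed, rnorm(n, 0, sd_noise))
    x <- x + noise
  }
  list(waveform = x, fs = fs)
}

#' Generate a labelled synthetic dataset of fixed-length segments
#'
#' Produces `per_class_counts[i]` segments for template `i`. Each segment
#' is synthesized at the native rate with a length chosen so that, once
#' its rate is relabelled to `fs_target` (see [relabel_rate()]), it is
#' exactly `segment_s` seconds long — the unit the feature pipeline and
#' the classifier consume. Per-segment variation comes from a random
#' pulse-onset phase, a small multiplicative jitter on the sweep band, and
#' an independent noise realisation; everything is reproducible from
#' `seed`.
#'
#' @param templates List of [call_template()] objects (one class each).
#' @param per_class_counts Integer vector of segment counts per template;
#'   skewed counts emulate the strong class imbalance of real surveys
#'   (largest:smallest around 60:1 in the survey this package models).
#' @param segment_s Segment length in seconds at `fs_target`.
#' @param seed Integer seed.
#' @param snr_db Signal-to-noise ratio per segment in dB.
#' @param fs_native,fs_target Native synthesis rate and pipeline rate.
#' @param band_jitter Relative half-width of the uniform jitter applied to
#'   each segment's sweep band (0 disables).
#' @return An object of class `echo_dataset`: list with `waveforms` (list
#'   of numeric vectors at `fs_native`), `labels` (factor of species
#'   names), `fs_native`, `fs_target`, `segment_s`.
#' @export
generate_dataset <- function(templates, per_class_counts, segment_s = 3,
                             seed = 0L, snr_db = 20, fs_native = 384000,
                             fs_target = 44100, band_jitter = 0.03) {
  if (length(templates) == 0) stop_invalid("at least one template is required")
  if (length(per_class_counts) != length(templates)) {
    stop_invalid("per_class_counts must have one entry per template")
  }
  if (any(per_class_counts < 1)) stop_invalid("per-class counts must be >= 1")
  species <- vapply(templates, function(t) t$species_name, character(1))
  native_duration <- segment_s * fs_target / fs_native
  waveforms <- vector("list", sum(per_class_counts))
  labels <- character(sum(per_class_counts))
  with_seed(seed, {
    pos <- 1L
    for (i in seq_along(templates)) {
      tpl <- templates[[i]]
      for (k in seq_len(per_class_counts[i])) {
        jit <- if (band_jitter > 0) 1 + runif(1, -band_jitter, band_jitter) else 1
        tpl_k <- tpl
        tpl_k$f_start <- tpl$f_start * jit
        tpl_k$f_end <- tpl$f_end * jit
        offset <- runif(1, 0, tpl$inter_pulse_interval)
        spec <- recording_spec(tpl_k, native_duration, snr_db = snr_db,
                               fs_native = fs_native,
                               seed = sample.int(.Machine$integer.max, 1))
        waveforms[[pos]] <- synthesize_recording(spec, onset_offset = offset)$waveform
        labels[pos] <- species[i]
        pos <- pos + 1L
      }
    }
  })
  structure(list(waveforms = waveforms,
                 labels = factor(labels, levels = species),
                 fs_native = fs_native, fs_target = fs_target,
                 segment_s = segment_s),
            class = "echo_dataset")
}

#' @export
print.echo_dataset <- function(x, ...) {
  cat(sprintf("<echo_dataset> %d segments of %.3g s (at %g Hz), %d classes\n",
              length(x$waveforms), x$segment_s, x$fs_target,
              nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Write a dataset to WAV files with a CSV manifest
#'
#' One 16-bit PCM WAV per segment plus `manifest.csv` with columns
#' `filename,species,fs_native`. Output is byte-identical across runs for
#' a dataset generated with the same seed.
#'
#' @param dataset An `echo_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset_wavs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "echo_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$waveforms)
  filenames <- sprintf("segment_%04d.wav", seq_len(n))
  for (i in seq_len(n)) {
    write_wav(dataset$waveforms[[i]], dataset$fs_native, file.path(dir, filenames[i]))
  }
  manifest <- data.frame(filename = filenames,
                         species = as.character(dataset$labels),
                         fs_native = dataset$fs_native)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
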