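# Minimal RIFF/WAVE codec (16-bit PCM, mono or multichannel).
# Ultrasound recorders such as the unit emulated here produce plain
# 16-bit PCM RIFF files, which is all the pipeline needs.

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped. Mono
#' input may be a plain numeric vector; multichannel input a matrix with
#' one column per channel.
#'
#' @param x Numeric vector or matrix of samples in `[-1, 1]`.
#' @param fs Sample rate in Hz (the nominal rate written to the header;
#'   see [relabel_rate()] for time-expansion semantics).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(x, fs, path) {
  assert_scalar_positive(fs, "fs")
  x <- as.matrix(x)
  n_channels <- ncol(x)
  x <- pmin(pmax(x, -1), 1)
  pcm <- as.integer(round(t(x) * 32767))  # interleave channels
  fs <- as.integer(round(fs))
  byte_rate <- fs * n_channels * 2L
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(n_channels * 2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path Input file path.
#' @return A list with `waveform` (numeric vector for mono, matrix with
#'   one column per channel otherwise, samples scaled to `[-1, 1]`) and
#'   `fs` (nominal sample rate in Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_invalid("'%s' is not a RIFF file", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_invalid("'%s' is not a WAVE file", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop_invalid("only PCM WAV files are supported")
      n_channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop_invalid("only 16-bit PCM is supported, got %d-bit", bits)
      remaining <- size - 16L
      if (remaining > 0) readBin(con, "raw", remaining)
    } else if (tag == "data") {
      samples <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (word aligned)
    }
  }
  if (is.null(fs) || is.null(samples)) stop_invalid("malformed WAV file '%s'", path)
  x <- samples / 32767
  if (n_channels > 1L) x <- t(matrix(x, nrow = n_channels))
  list(waveform = x, fs = fs)
}
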