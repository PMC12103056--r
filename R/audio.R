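#' Audio buffer
#'
#' Container for a sampled 1- or 2-channel waveform. Samples are stored as a
#' numeric matrix with one column per channel and must lie in \[-1, 1\].
#'
#' @param samples numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `audio_buffer` with elements `samples`
#'   (matrix, samples x channels) and `sample_rate`.
#' @export
audio_buffer <- function(samples, sample_rate = 44100) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric vector or matrix")
  if (!ncol(samples) %in% c(1L, 2L))
    stop("audio_buffer supports 1 or 2 channels, got ", ncol(samples))
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (max(abs(samples)) > 1 + 1e-12)
    stop("samples must lie in [-1, 1]")
  structure(
    list(samples = samples, sample_rate = sample_rate),
    class = "audio_buffer"
  )
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer: %d samples, %d channel(s), %g Hz, %.1f ms>\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              1000 * nrow(x$samples) / x$sample_rate))
  invisible(x)
}

#' @rdname audio_buffer
#' @param x an `audio_buffer`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname audio_buffer
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname audio_buffer
#' @export
duration_ms <- function(x) 1000 * nrow(x$samples) / x$sample_rate

# Raised-cosine on/off ramp envelope for a channel of n samples.
# ramp_ms = 0 returns all ones.
raised_cosine_env <- function(n, ramp_ms, sample_rate) {
  env <- rep(1, n)
  n_ramp <- round(ramp_ms * sample_rate / 1000)
  if (n_ramp > 0) {
    n_ramp <- min(n_ramp, floor(n / 2))
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    env[seq_len(n_ramp)] <- ramp
    env[n - n_ramp + seq_len(n_ramp)] <- rev(ramp)
  }
  env
}

# Peak-normalize a sample matrix to the given peak (default 0.9; digital
# presentation levels are metadata only, there is no hardware calibration).
peak_normalize <- function(samples, peak = 0.9) {
  m <- max(abs(samples))
  if (m > 0) samples * (peak / m) else samples
}

#' Write an audio buffer as a 16-bit PCM WAV file
#'
#' Minimal canonical RIFF/WAVE writer (16-bit little-endian PCM,
#' interleaved channels).
#'
#' @param buf an `audio_buffer`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buf, path) {
  stopifnot(inherits(buf, "audio_buffer"))
  ch <- ncol(buf$samples)
  sr <- as.integer(buf$sample_rate)
  # interleave channels, scale to int16
  x <- as.vector(t(buf$samples))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32767))))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(ch, con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * ch * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(ch * 2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file into an audio buffer
#'
#' @param path WAV file path (16-bit PCM as written by [write_wav()]).
#' @return An `audio_buffer`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  ch <- NULL; sr <- NULL; bits <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported")
      ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (bits != 16L) stop("only 16-bit PCM is supported")
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(pcm)) stop("no data chunk found in ", path)
  x <- pcm / 32767
  audio_buffer(matrix(x, ncol = ch, byrow = TRUE), sample_rate = sr)
}
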