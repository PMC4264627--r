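#' Audio signal container
#'
#' Bundles a mono sample vector with its sample rate. Samples are stored as
#' doubles but are expected to lie in the signed 16-bit PCM range
#' (-32768..32767) whenever the signal is written to disk; no normalization
#' to \[-1, 1\] is performed anywhere in the package, so frame log-energies
#' are computed on the raw integer-scale amplitudes.
#'
#' @param samples numeric vector of sample amplitudes.
#' @param sample_rate sampling rate in Hz (canonical value 11025).
#' @return an object of class `audio_signal`.
#' @examples
#' sig <- audio_signal(sin(2 * pi * 440 * (0:11024) / 11025) * 8000, 11025)
#' audio_duration(sig)
#' @export
audio_signal <- function(samples, sample_rate = 11025L) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate, audio_duration(x)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an [audio_signal()].
#' @return duration in seconds.
#' @export
audio_duration <- function(signal) {
  length(signal$samples) / signal$sample_rate
}

PCM16_MIN <- -32768
PCM16_MAX <- 32767

read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Parses the RIFF container directly: the canonical input format is mono
#' 16-bit PCM at 11025 Hz. Other sample rates are accepted (with a warning
#' unless `warn_rate = FALSE`); no resampling is performed. Multi-channel
#' files are rejected unless `mixdown = TRUE`, in which case channels are
#' averaged.
#'
#' @param path path to a `.wav` file.
#' @param mixdown average multi-channel audio down to mono instead of
#'   raising an error.
#' @param warn_rate warn when the sample rate differs from 11025 Hz.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path, mixdown = FALSE, warn_rate = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file (missing RIFF tag): ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file (missing WAVE tag): ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr)) break
    if (hdr$id == "fmt ") {
      body <- readBin(con, "raw", hdr$size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, size = 2L, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, size = 2L, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, size = 2L, endian = "little")
      )
    } else if (hdr$id == "data") {
      data_raw <- readBin(con, "raw", hdr$size)
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, where = hdr$size + hdr$size %% 2L, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV: no fmt chunk in ", path)
  if (is.null(data_raw)) stop("malformed WAV: no data chunk in ", path)
  if (fmt$audio_format != 1L)
    stop("unsupported WAV encoding (audio format tag ", fmt$audio_format,
         "); only uncompressed PCM is supported")
  if (fmt$bits != 16L)
    stop("unsupported bit depth ", fmt$bits, "; only 16-bit PCM is supported")
  samples <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                     size = 2L, signed = TRUE, endian = "little")
  if (fmt$n_channels > 1L) {
    if (!mixdown)
      stop("multi-channel WAV (", fmt$n_channels,
           " channels); pass mixdown = TRUE to average to mono")
    samples <- colMeans(matrix(as.numeric(samples), nrow = fmt$n_channels))
  }
  if (warn_rate && fmt$sample_rate != 11025L)
    warning("sample rate is ", fmt$sample_rate, " Hz, not the canonical 11025 Hz; ",
            "no resampling is applied")
  audio_signal(samples, fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples outside the signed 16-bit range raise an error unless
#' `clip = TRUE`, in which case they are clamped. Fractional samples are
#' rounded to the nearest integer.
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param clip clamp out-of-range samples instead of erroring.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, clip = FALSE) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- round(signal$samples)
  if (any(x < PCM16_MIN | x > PCM16_MAX)) {
    if (!clip)
      stop("samples exceed the 16-bit PCM range [-32768, 32767]; ",
           "pass clip = TRUE to clamp")
    x <- pmin(pmax(x, PCM16_MIN), PCM16_MAX)
  }
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  sr <- as.integer(round(signal$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")        # PCM
  writeBin(1L, con, size = 2L, endian = "little")        # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4L, endian = "little")  # byte rate
  writeBin(2L, con, size = 2L, endian = "little")        # block align
  writeBin(16L, con, size = 2L, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(as.integer(x), con, size = 2L, endian = "little")
  invisible(path)
}

#' Number of full analysis frames in a signal
#'
#' @param len signal length in samples.
#' @param frame_size frame length in samples.
#' @param hop frame advance in samples.
#' @return the frame count `floor((len - frame_size) / hop) + 1`.
#' @export
n_frames <- function(len, frame_size = 256L, hop = 128L) {
  if (hop <= 0 || hop > frame_size) stop("hop must satisfy 0 < hop <= frame_size")
  if (len < frame_size) stop("signal shorter than one frame (", len, " < ", frame_size, ")")
  as.integer((len - frame_size) %/% hop + 1L)
}

#' Slice a signal into fixed half-overlapping frames
#'
#' Frame `i` (0-based) starts at sample `i * hop`; trailing samples that do
#' not fill a whole frame are dropped. The default 256-sample frame with a
#' 128-sample hop at 11025 Hz gives a frame period of about 0.0116 s.
#'
#' @param signal an [audio_signal()] or bare numeric vector.
#' @param frame_size frame length in samples (default 256).
#' @param hop frame advance in samples (default 128, i.e. half-frame overlap).
#' @return a numeric matrix with one row per frame and `frame_size` columns.
#' @export
frame_signal <- function(signal, frame_size = 256L, hop = 128L) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
  nf <- n_frames(length(x), frame_size, hop)
  starts <- (seq_len(nf) - 1L) * hop
  idx <- outer(starts, seq_len(frame_size), `+`)
  matrix(x[idx], nrow = nf, ncol = frame_size)
}
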