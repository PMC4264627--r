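#' Feature extraction configuration
#'
#' Collects the framing and spectral-analysis parameters used by
#' [extract_features()]. The defaults reproduce the canonical analysis
#' chain: 256-sample frames with half-frame overlap, a 256-point Hann
#' window, a 32-filter mel filterbank on the magnitude spectrum, 12 MFCCs
#' plus a frame log-energy, and first differences of both. No preemphasis
#' filter is applied.
#'
#' @param frame_size frame length in samples.
#' @param hop frame advance in samples.
#' @param n_filters number of triangular mel filters.
#' @param n_mfcc number of retained cepstral coefficients (coefficient 0 is
#'   always discarded in favour of the time-domain log-energy).
#' @param floor numeric floor applied inside logarithms so silent frames and
#'   empty filterbank channels stay finite.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(frame_size = 256L, hop = 128L, n_filters = 32L,
                           n_mfcc = 12L, floor = 1e-10) {
  stopifnot(frame_size >= 2L, hop > 0L, hop <= frame_size,
            n_filters >= 1L, n_mfcc >= 1L, floor > 0)
  structure(list(frame_size = as.integer(frame_size), hop = as.integer(hop),
                 n_filters = as.integer(n_filters), n_mfcc = as.integer(n_mfcc),
                 floor = floor),
            class = "feature_config")
}

#' Symmetric Hann window
#'
#' `w[j] = 0.5 - 0.5 cos(2 pi j / (n - 1))` for `j = 0 .. n-1`.
#'
#' @param n window length (>= 2).
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  if (n < 2L) stop("window length must be >= 2")
  j <- seq_len(n) - 1L
  0.5 - 0.5 * cos(2 * pi * j / (n - 1L))
}

#' Magnitude spectrum of a windowed frame
#'
#' Multiplies the frame by `window` and returns the DFT magnitudes on the
#' non-redundant half spectrum, bins `0 .. n/2`.
#'
#' @param frame numeric vector, one analysis frame.
#' @param window window weights of the same length (default Hann); pass
#'   `rep(1, length(frame))` for a rectangular window.
#' @return numeric vector of `length(frame)/2 + 1` magnitudes.
#' @export
magnitude_spectrum <- function(frame, window = hann_window(length(frame))) {
  n <- length(frame)
  if (length(window) != n) stop("window length does not match frame length")
  Mod(stats::fft(frame * window))[seq_len(n %/% 2L + 1L)]
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Build a triangular mel filterbank
#'
#' Filter centres are equally spaced on the mel scale
#' `mel(f) = 2595 log10(1 + f/700)` between 0 Hz and the Nyquist frequency;
#' each unit-peak triangle spans from the previous centre to the next and is
#' applied to the magnitude (not power) spectrum.
#'
#' @param n_filters number of filters (default 32).
#' @param n_fft DFT length (default 256, must be even).
#' @param sample_rate sampling rate in Hz.
#' @return a list of class `mel_filterbank` with a `weights` matrix of
#'   `n_filters` rows by `n_fft/2 + 1` spectral-bin columns and the vector
#'   of `centers_hz`.
#' @export
build_mel_filterbank <- function(n_filters = 32L, n_fft = 256L, sample_rate = 11025) {
  stopifnot(n_filters >= 1L, n_fft %% 2L == 0L, sample_rate > 0)
  nyquist <- sample_rate / 2
  edges_hz <- hz_of_mel(seq(mel_of_hz(0), mel_of_hz(nyquist), length.out = n_filters + 2L))
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  W <- matrix(0, nrow = n_filters, ncol = n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges_hz[i]; c0 <- edges_hz[i + 1L]; hi <- edges_hz[i + 2L]
    rise <- (bin_hz - lo) / (c0 - lo)
    fall <- (hi - bin_hz) / (hi - c0)
    W[i, ] <- pmax(0, pmin(rise, fall))
    if (all(W[i, ] == 0))
      stop("mel filter ", i, " covers no spectral bin; ",
           "reduce n_filters or increase n_fft")
  }
  structure(list(weights = W, centers_hz = edges_hz[2:(n_filters + 1L)],
                 n_fft = as.integer(n_fft), sample_rate = sample_rate),
            class = "mel_filterbank")
}

# DCT-II of each column of V via the even/odd index reordering that turns a
# length-N DCT into a single length-N complex DFT, with orthonormal scaling.
dct2_via_fft <- function(V) {
  V <- as.matrix(V)
  n <- nrow(V)
  ord <- c(seq(1L, n, by = 2L), seq(if (n %% 2L == 0L) n else n - 1L, 2L, by = -2L))
  U <- stats::mvfft(V[ord, , drop = FALSE])
  k <- seq_len(n) - 1L
  phase <- exp(-1i * pi * k / (2 * n))
  C <- Re(U * phase)
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  C * scale
}

#' MFCCs from a magnitude spectrum
#'
#' Applies the mel filterbank to the magnitude spectrum, takes natural logs
#' (floored at `floor`), and computes the orthonormal DCT-II of the log
#' filterbank outputs through a reordered FFT. Coefficients `1..n_mfcc` are
#' returned; coefficient 0 (overall frame energy) is discarded because a
#' separate time-domain log-energy measure is used instead.
#'
#' @param mag magnitude spectrum from [magnitude_spectrum()].
#' @param fb a [build_mel_filterbank()] object with matching `n_fft`.
#' @param n_mfcc number of coefficients to keep.
#' @param floor log floor.
#' @return numeric vector of `n_mfcc` cepstral coefficients.
#' @export
mfcc_from_spectrum <- function(mag, fb, n_mfcc = 12L, floor = 1e-10) {
  if (length(mag) != ncol(fb$weights))
    stop("spectrum length ", length(mag), " does not match filterbank bins ",
         ncol(fb$weights))
  logfb <- log(pmax(fb$weights %*% cbind(mag), floor))
  dct2_via_fft(logfb)[1L + seq_len(n_mfcc), 1L]
}

#' Frame log-energy
#'
#' Natural log of the sum of squared time-domain samples in the frame,
#' computed on the raw amplitude scale. An all-zero frame returns
#' `log(floor)` so every feature stays finite.
#'
#' @param frame numeric vector of samples.
#' @param floor energy floor inside the log.
#' @return a single log-energy value.
#' @export
log_energy <- function(frame, floor = 1e-10) {
  log(max(sum(frame^2), floor))
}

#' First differences of a per-frame quantity
#'
#' Interior frames use the central difference `(f[i+1] - f[i-1]) / 2`; at the
#' sequence boundaries the difference between immediate neighbours is used
#' (`f[2] - f[1]` for the first frame, `f[T] - f[T-1]` for the last).
#'
#' @param x numeric vector (one scalar per frame) or matrix (one row per
#'   frame).
#' @return an object of the same shape holding the differences.
#' @export
first_differences <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("need at least 2 frames for first differences")
    return(apply(x, 2L, first_differences))
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 frames for first differences")
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d
}

#' Extract the 26-dimensional feature sequence from audio
#'
#' Runs the full per-frame analysis chain: framing, Hann windowing, DFT
#' magnitude, mel filterbank, log, DCT (12 MFCCs), time-domain log-energy,
#' and first differences of all 13 static features. Returns a `T x 26`
#' matrix with columns `mfcc1..mfcc12, logE, d_mfcc1..d_mfcc12, d_logE`.
#'
#' @param signal an [audio_signal()].
#' @param config a [feature_config()].
#' @return a numeric matrix of class `feature_seq` with attributes
#'   `frame_size`, `hop` and `sample_rate`.
#' @export
extract_features <- function(signal, config = feature_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  frames <- frame_signal(signal, config$frame_size, config$hop)
  if (nrow(frames) < 2L)
    stop("signal too short: at least 2 frames are needed for delta features")
  w <- hann_window(config$frame_size)
  fb <- build_mel_filterbank(config$n_filters, config$frame_size, signal$sample_rate)
  n_bins <- config$frame_size %/% 2L + 1L
  spec <- Mod(stats::mvfft(t(frames) * w))[seq_len(n_bins), , drop = FALSE]
  logfb <- log(pmax(fb$weights %*% spec, config$floor))
  mfcc <- t(dct2_via_fft(logfb)[1L + seq_len(config$n_mfcc), , drop = FALSE])
  e <- log(pmax(rowSums(frames^2), config$floor))
  static <- cbind(mfcc, e)
  feats <- cbind(static, first_differences(static))
  colnames(feats) <- c(paste0("mfcc", seq_len(config$n_mfcc)), "logE",
                       paste0("d_mfcc", seq_len(config$n_mfcc)), "d_logE")
  structure(feats, class = c("feature_seq", "matrix", "array"),
            frame_size = config$frame_size, hop = config$hop,
            sample_rate = signal$sample_rate)
}

#' Write a feature sequence to a columnar text file
#'
#' A small self-describing format so training and decoding can run as
#' separate command-line steps: `#`-prefixed header lines record
#' `frame_size`, `hop` and `sample_rate`, followed by one tab-separated row
#' per frame at full double precision.
#'
#' @param x a `feature_seq` from [extract_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_size: %d", attr(x, "frame_size")),
               sprintf("# hop: %d", attr(x, "hop")),
               sprintf("# sample_rate: %.17g", attr(x, "sample_rate")),
               paste0("# columns: ", paste(colnames(x), collapse = "\t"))), con)
  utils::write.table(format(unclass(x), digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature sequence written by [write_features()]
#' @param path input path.
#' @return a `feature_seq` matrix.
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  cols <- strsplit(sub("^# columns: ", "", grep("^# columns:", hdr, value = TRUE)), "\t")[[1]]
  colnames(m) <- cols
  structure(m, class = c("feature_seq", "matrix", "array"),
            frame_size = as.integer(get("frame_size")),
            hop = as.integer(get("hop")),
            sample_rate = as.numeric(get("sample_rate")))
}
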