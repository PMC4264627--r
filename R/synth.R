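# Seeded synthetic audio corpus generator.
#
# Emulates the structure of an ambulatory cough-monitoring database:
# variable-length isolated cough clips (transient two-phase noise bursts
# with a band emphasis), fixed 6-s blocks of stationary colored background
# noise with slow amplitude modulation, and near-zero silence blocks. The
# generator aims for statistical separability of the three classes, not
# clinical realism; amplitudes are on the raw signed 16-bit scale.

#' Synthetic corpus specification
#'
#' Defaults mirror the scale of the study corpus the package emulates: 140
#' isolated cough clips (110 for training plus 30 held out), fixed 6-s
#' background/silence blocks at 11025 Hz, and cough durations of 0.2-0.8 s.
#'
#' @param seed RNG seed consumed by [make_corpus()] and
#'   [make_labeled_stream()].
#' @param n_cough_clips number of isolated cough clips.
#' @param n_background_blocks,n_silence_blocks number of fixed-length
#'   training blocks per class.
#' @param cough_duration_range cough duration bounds in seconds.
#' @param block_seconds training/evaluation block length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param snr_db cough-to-background RMS level (dB) used when embedding
#'   events into a stream.
#' @param background_rms,silence_rms RMS amplitudes of the two stationary
#'   classes (16-bit sample units); the defaults keep silence more than
#'   20 dB below background.
#' @param cough_peak_range peak amplitude range for isolated cough clips.
#' @return a list of class `corpus_spec`.
#' @export
corpus_spec <- function(seed = 1L, n_cough_clips = 140L,
                        n_background_blocks = 20L, n_silence_blocks = 20L,
                        cough_duration_range = c(0.2, 0.8),
                        block_seconds = 6, sample_rate = 11025,
                        snr_db = 20, background_rms = 400, silence_rms = 8,
                        cough_peak_range = c(5000, 12000)) {
  stopifnot(n_cough_clips >= 1L, n_background_blocks >= 1L,
            n_silence_blocks >= 1L, all(cough_duration_range > 0),
            block_seconds > 0, sample_rate > 0, background_rms > 0,
            silence_rms > 0)
  structure(list(seed = as.integer(seed), n_cough_clips = as.integer(n_cough_clips),
                 n_background_blocks = as.integer(n_background_blocks),
                 n_silence_blocks = as.integer(n_silence_blocks),
                 cough_duration_range = cough_duration_range,
                 block_seconds = block_seconds, sample_rate = sample_rate,
                 snr_db = snr_db, background_rms = background_rms,
                 silence_rms = silence_rms, cough_peak_range = cough_peak_range),
            class = "corpus_spec")
}

rms <- function(x) sqrt(mean(x^2))

#' Generate one isolated synthetic cough clip
#'
#' A two-phase transient: an explosive burst with a ~3 ms attack and fast
#' exponential decay, followed by a weaker second burst, carried by
#' broadband noise band-emphasized between roughly 0.8 and 3.2 kHz. The
#' clip duration is drawn uniformly from `cough_duration_range`. Consumes
#' the current RNG stream, so results are deterministic given the RNG
#' state.
#'
#' @param spec a [corpus_spec()].
#' @return an [audio_signal()].
#' @export
make_cough_clip <- function(spec = corpus_spec()) {
  sr <- spec$sample_rate
  dur <- stats::runif(1, spec$cough_duration_range[1], spec$cough_duration_range[2])
  n <- max(round(dur * sr), 32L)
  t <- (seq_len(n) - 1L) / sr
  bp <- signal::butter(2, c(800, 3200) / (sr / 2), type = "pass")
  carrier <- signal::filtfilt(bp, stats::rnorm(n))
  carrier <- carrier / max(abs(carrier))
  attack <- pmin(t / 0.003, 1)
  tau1 <- dur / 8
  burst1 <- attack * exp(-t / tau1)
  t0 <- 0.45 * dur
  tau2 <- dur / 5
  burst2 <- 0.4 * ifelse(t >= t0, exp(-(t - t0) / tau2), 0)
  env <- burst1 + burst2
  peak <- stats::runif(1, spec$cough_peak_range[1], spec$cough_peak_range[2])
  audio_signal(peak * env * carrier, sr)
}

colored_noise <- function(n, cutoff_norm = 0.15) {
  lp <- signal::butter(2, cutoff_norm, type = "low")
  as.numeric(signal::filtfilt(lp, stats::rnorm(n)))
}

#' Generate one fixed-length background block
#'
#' Stationary low-pass colored noise (speech-babble-like spectral tilt)
#' with slow sinusoidal amplitude modulation, scaled to
#' `spec$background_rms`.
#'
#' @param spec a [corpus_spec()].
#' @return an [audio_signal()] of exactly `block_seconds` duration.
#' @export
make_background_block <- function(spec = corpus_spec()) {
  sr <- spec$sample_rate
  n <- round(spec$block_seconds * sr)
  x <- colored_noise(n)
  t <- (seq_len(n) - 1L) / sr
  fm <- stats::runif(1, 0.1, 0.5)
  am <- 1 + 0.35 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
  x <- x * am
  audio_signal(x * spec$background_rms / rms(x), sr)
}

#' Generate one fixed-length silence block
#'
#' Very low-amplitude white noise (sensor/quantization hiss), at least
#' 20 dB below the background level at the default spec.
#'
#' @param spec a [corpus_spec()].
#' @return an [audio_signal()].
#' @export
make_silence_block <- function(spec = corpus_spec()) {
  n <- round(spec$block_seconds * spec$sample_rate)
  audio_signal(stats::rnorm(n, 0, spec$silence_rms), spec$sample_rate)
}

#' Generate a full labeled corpus
#'
#' Seeds the RNG from `spec$seed` and generates all cough clips,
#' background blocks and silence blocks, plus a train/holdout split of the
#' cough clips (by default the last `n_test_coughs` clips are withheld).
#'
#' @param spec a [corpus_spec()].
#' @param n_test_coughs number of cough clips withheld for testing
#'   (default 30, capped at half the clips).
#' @return a list of class `cough_corpus` with `cough_clips`,
#'   `background_blocks`, `silence_blocks`, `train_idx`, `test_idx` and
#'   the `spec`.
#' @export
make_corpus <- function(spec = corpus_spec(), n_test_coughs = 30L) {
  set.seed(spec$seed)
  coughs <- replicate(spec$n_cough_clips, make_cough_clip(spec), simplify = FALSE)
  bgs <- replicate(spec$n_background_blocks, make_background_block(spec),
                   simplify = FALSE)
  sils <- replicate(spec$n_silence_blocks, make_silence_block(spec),
                    simplify = FALSE)
  n_test <- min(n_test_coughs, spec$n_cough_clips %/% 2L)
  test_idx <- spec$n_cough_clips - seq_len(n_test) + 1L
  structure(list(cough_clips = coughs, background_blocks = bgs,
                 silence_blocks = sils,
                 train_idx = setdiff(seq_len(spec$n_cough_clips), test_idx),
                 test_idx = sort(test_idx), spec = spec),
            class = "cough_corpus")
}

#' @export
print.cough_corpus <- function(x, ...) {
  cat(sprintf("cough_corpus (seed %d): %d cough clips (%d train / %d test), %d background + %d silence blocks of %g s\n",
              x$spec$seed, length(x$cough_clips), length(x$train_idx),
              length(x$test_idx), length(x$background_blocks),
              length(x$silence_blocks), x$spec$block_seconds))
  invisible(x)
}

#' Generate a continuous stream with ground-truth cough events
#'
#' Builds `minutes` of modulated background noise and mixes `n_events`
#' cough clips in at `spec$snr_db` dB above the background RMS, at random
#' non-overlapping offsets. Seeds the RNG from `spec$seed` unless
#' `use_current_rng = TRUE`.
#'
#' @param spec a [corpus_spec()].
#' @param n_events number of embedded coughs (0 gives a cough-free
#'   stream).
#' @param minutes stream length in minutes.
#' @param use_current_rng consume the current RNG stream instead of
#'   seeding from `spec$seed`.
#' @return a list of class `labeled_stream` with `signal` and `events`
#'   (data frame: `start_sample`, `end_sample`, `start_s`, `end_s`).
#' @export
make_labeled_stream <- function(spec = corpus_spec(), n_events = 10L,
                                minutes = 2, use_current_rng = FALSE) {
  if (!use_current_rng) set.seed(spec$seed)
  sr <- spec$sample_rate
  n <- round(minutes * 60 * sr)
  t <- (seq_len(n) - 1L) / sr
  bg <- colored_noise(n)
  fm <- stats::runif(1, 0.1, 0.5)
  bg <- bg * (1 + 0.35 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi)))
  bg <- bg * spec$background_rms / rms(bg)

  events <- data.frame(start_sample = integer(0), end_sample = integer(0))
  if (n_events > 0L) {
    clips <- replicate(n_events, make_cough_clip(spec), simplify = FALSE)
    target_rms <- spec$background_rms * 10^(spec$snr_db / 20)
    taken <- matrix(numeric(0), ncol = 2L)
    for (clip in clips) {
      len <- length(clip$samples)
      placed <- FALSE
      for (try in seq_len(200L)) {
        start <- sample.int(n - len, 1L)
        if (nrow(taken) == 0L ||
            all(start > taken[, 2L] | (start + len - 1L) < taken[, 1L])) {
          x <- clip$samples * target_rms / rms(clip$samples)
          bg[start:(start + len - 1L)] <- bg[start:(start + len - 1L)] + x
          taken <- rbind(taken, c(start, start + len - 1L))
          events <- rbind(events, data.frame(start_sample = start,
                                             end_sample = start + len - 1L))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n_events, " non-overlapping events in ",
             minutes, " minutes of audio")
    }
    events <- events[order(events$start_sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  events$start_s <- (events$start_sample - 1L) / sr
  events$end_s <- events$end_sample / sr
  structure(list(signal = audio_signal(pmin(pmax(bg, -32768), 32767), sr),
                 events = events, spec = spec),
            class = "labeled_stream")
}

#' Write a corpus to a directory of WAV files with a manifest
#'
#' Creates `cough_NNN.wav`, `background_NNN.wav` and `silence_NNN.wav`
#' files plus a tab-separated `manifest.tsv` (`path`, `class`, `split`,
#' `duration_s`).
#'
#' @param corpus a [make_corpus()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(sig, class, i, split) {
    fn <- sprintf("%s_%03d.wav", class, i)
    write_wav(sig, file.path(dir, fn), clip = TRUE)
    data.frame(path = fn, class = class, split = split,
               duration_s = audio_duration(sig))
  }
  for (i in seq_along(corpus$cough_clips))
    rows[[length(rows) + 1L]] <-
      emit(corpus$cough_clips[[i]], "cough", i,
           if (i %in% corpus$test_idx) "test" else "train")
  for (i in seq_along(corpus$background_blocks))
    rows[[length(rows) + 1L]] <- emit(corpus$background_blocks[[i]], "background", i, "train")
  for (i in seq_along(corpus$silence_blocks))
    rows[[length(rows) + 1L]] <- emit(corpus$silence_blocks[[i]], "silence", i, "train")
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
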