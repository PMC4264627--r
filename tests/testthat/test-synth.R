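# Synthetic corpus generator: determinism, envelope shape, separability.

test_that("generation is deterministic under a fixed seed at every level", {
  spec <- corpus_spec(seed = 42, n_cough_clips = 3, n_background_blocks = 2,
                      n_silence_blocks = 2)
  c1 <- make_corpus(spec)
  c2 <- make_corpus(spec)
  expect_identical(c1$cough_clips, c2$cough_clips)
  expect_identical(c1$background_blocks, c2$background_blocks)
  expect_identical(c1$silence_blocks, c2$silence_blocks)
  s1 <- make_labeled_stream(spec, n_events = 3, minutes = 0.25)
  s2 <- make_labeled_stream(spec, n_events = 3, minutes = 0.25)
  expect_identical(s1$signal$samples, s2$signal$samples)
  expect_identical(s1$events, s2$events)
  set.seed(1); a <- make_cough_clip(spec)
  set.seed(1); b <- make_cough_clip(spec)
  expect_identical(a$samples, b$samples)
})

test_that("cough clips are front-loaded transients within the configured duration", {
  spec <- corpus_spec(seed = 1)
  set.seed(11)
  for (rep in 1:40) {
    clip <- make_cough_clip(spec)
    dur <- audio_duration(clip)
    expect_gte(dur, 0.2 - 1e-3)
    expect_lte(dur, 0.8 + 1e-3)
    # short-time energy envelope peaks within the first 25% of the clip
    n <- length(clip$samples)
    win <- max(32L, n %/% 50L)
    e <- vapply(seq(1L, n - win, by = win), function(i)
      sum(clip$samples[i:(i + win - 1L)]^2), numeric(1))
    expect_lte(which.max(e) / length(e), 0.25)
    expect_true(all(abs(clip$samples) <= 32767))
  }
})

test_that("blocks have the exact fixed length and a >= 20 dB silence margin", {
  spec <- corpus_spec(seed = 2)
  set.seed(12)
  bg <- make_background_block(spec)
  sil <- make_silence_block(spec)
  expect_identical(length(bg$samples), 66150L)
  expect_identical(length(sil$samples), 66150L)
  rms <- function(x) sqrt(mean(x^2))
  expect_gte(20 * log10(rms(bg$samples) / rms(sil$samples)), 20)
})

test_that("cough and background spectra are distinguishable", {
  # spectral centroid of the band-emphasized cough burst sits well above the
  # low-passed background's; this is the separability the recognizer needs
  spec <- corpus_spec(seed = 3)
  set.seed(13)
  centroid <- function(sig) {
    f <- extract_features(sig)
    m <- colMeans(f[, 1:13])
    fr <- frame_signal(sig)
    mags <- Mod(stats::mvfft(t(fr) * hann_window(256)))[1:129, , drop = FALSE]
    freqs <- (0:128) * sig$sample_rate / 256
    mean(colSums(mags * freqs) / colSums(mags))
  }
  for (rep in 1:5) {
    expect_gt(centroid(make_cough_clip(spec)),
              centroid(make_background_block(spec)) + 500)
  }
})

test_that("a mean-feature Gaussian classifier separates cough from background", {
  spec <- corpus_spec(seed = 4, n_cough_clips = 30, n_background_blocks = 30,
                      n_silence_blocks = 1)
  corpus <- make_corpus(spec, n_test_coughs = 0)
  mean_feat <- function(sig) colMeans(extract_features(sig))
  Xc <- t(vapply(corpus$cough_clips, mean_feat, numeric(26)))
  Xb <- t(vapply(corpus$background_blocks, mean_feat, numeric(26)))
  fit <- function(X) list(mu = colMeans(X),
                          v = pmax(apply(X, 2, stats::var), 1e-8))
  gc <- fit(Xc); gb <- fit(Xb)
  score <- function(x, g) -0.5 * sum(log(g$v)) - 0.5 * sum((x - g$mu)^2 / g$v)
  pred_c <- apply(Xc, 1, function(x) score(x, gc) > score(x, gb))
  pred_b <- apply(Xb, 1, function(x) score(x, gb) > score(x, gc))
  expect_gte(mean(c(pred_c, pred_b)), 0.95)
})

test_that("labeled streams embed disjoint in-bounds events at the target level", {
  spec <- corpus_spec(seed = 5)
  st <- make_labeled_stream(spec, n_events = 8, minutes = 0.5)
  n <- length(st$signal$samples)
  expect_identical(n, as.integer(round(0.5 * 60 * 11025)))
  ev <- st$events
  expect_identical(nrow(ev), 8L)
  expect_true(all(ev$start_sample >= 1 & ev$end_sample <= n))
  o <- order(ev$start_sample)
  expect_true(all(ev$start_sample[o][-1] > ev$end_sample[o][-8]))
  # a cough-free stream carries no events and stays background-level
  quiet <- make_labeled_stream(spec, n_events = 0, minutes = 0.1)
  expect_identical(nrow(quiet$events), 0L)
  expect_lt(sqrt(mean(quiet$signal$samples^2)), 3 * spec$background_rms)
  # impossible packing is rejected
  expect_error(make_labeled_stream(corpus_spec(seed = 6), n_events = 50,
                                   minutes = 0.05), "non-overlapping")
})

test_that("corpora round-trip to a WAV directory with a manifest", {
  spec <- corpus_spec(seed = 8, n_cough_clips = 2, n_background_blocks = 1,
                      n_silence_blocks = 1)
  corpus <- make_corpus(spec, n_test_coughs = 1)
  dir <- withr::local_tempdir()
  manifest <- write_corpus(corpus, dir)
  expect_identical(nrow(manifest), 4L)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_wav(file.path(dir, "cough_001.wav"))
  expect_equal(back$samples, round(corpus$cough_clips[[1]]$samples))
})
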