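# MFCC / log-energy feature extraction.

test_that("Hann window has the symmetric cosine form", {
  w <- hann_window(256)
  expect_equal(w[1], 0)
  expect_equal(w[256], 0)
  expect_equal(w, rev(w))                      # symmetry w[j] = w[n-1-j]
  expect_gt(min(w[128:129]), 0.999)            # peak ~1 at the midpoint
  j <- 0:255
  expect_equal(sum(w), sum(0.5 - 0.5 * cos(2 * pi * j / 255)))
  expect_error(hann_window(1), ">= 2")
})

test_that("magnitude spectrum matches a naive O(n^2) DFT", {
  set.seed(201)
  x <- rnorm(64)
  expect_equal(magnitude_spectrum(x, rep(1, 64)), naive_dft_mag(x),
               tolerance = 1e-12)
  expect_equal(magnitude_spectrum(rep(0, 64)), rep(0, 33))
  # bin-aligned sinusoid concentrates at its bin under a rectangular window
  k0 <- 5L
  s <- sin(2 * pi * k0 * (0:63) / 64)
  mag <- magnitude_spectrum(s, rep(1, 64))
  expect_identical(which.max(mag) - 1L, k0)
  expect_lt(max(mag[-(k0 + 1)]) / mag[k0 + 1], 1e-10)
  expect_error(magnitude_spectrum(rnorm(10), rep(1, 12)), "match")
})

test_that("mel filterbank centres match an independent mel-spacing computation", {
  fb <- build_mel_filterbank(32, 256, 11025)
  expect_identical(nrow(fb$weights), 32L)
  expect_identical(ncol(fb$weights), 129L)
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centers <- imel(seq(mel(0), mel(11025 / 2), length.out = 34))[2:33]
  expect_equal(fb$centers_hz, centers, tolerance = 1e-12)
  expect_true(all(diff(fb$centers_hz) > 0))
  expect_true(all(fb$weights >= 0))
  # unit-peak triangles, sampled at the DFT bin grid: the sampled maximum
  # can fall short of the continuous peak but never exceed it
  peaks <- apply(fb$weights, 1, max)
  expect_true(all(peaks <= 1 + 1e-12))
  expect_true(all(peaks > 0.3))
  # each filter is triangular: one run up, one run down
  for (i in c(1, 10, 32)) {
    nz <- fb$weights[i, fb$weights[i, ] > 0]
    expect_true(all(diff(sign(diff(c(0, nz, 0))) <= 0) >= 0))
  }
  expect_lte(max(which(fb$weights[32, ] > 0)), 129)
})

test_that("degenerate filterbanks behave and over-resolved ones error", {
  fb1 <- build_mel_filterbank(1, 256, 11025)
  expect_identical(nrow(fb1$weights), 1L)
  expect_gt(sum(fb1$weights > 0), 100)   # spans essentially the whole band
  expect_error(build_mel_filterbank(200, 256, 11025), "no spectral bin")
})

test_that("reordered-FFT MFCC path equals the direct-sum DCT-II oracle", {
  set.seed(202)
  for (rep in 1:20) {
    v <- rnorm(32, sd = 3)
    got <- coughmon:::dct2_via_fft(cbind(v))[, 1]
    want <- direct_dct2(v)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # constant log-filterbank vector has zero energy in all k >= 1 coefficients
  fb <- build_mel_filterbank(32, 256, 11025)
  flat <- coughmon:::dct2_via_fft(cbind(rep(2.5, 32)))[-1, 1]
  expect_equal(flat, rep(0, 31), tolerance = 1e-12)
  # through the public interface: coefficients 1..12 of a random spectrum
  mag <- abs(rnorm(129, sd = 10))
  want <- direct_dct2(log(pmax(fb$weights %*% mag, 1e-10)))[2:13]
  expect_equal(mfcc_from_spectrum(mag, fb), want, tolerance = 1e-10)
  expect_error(mfcc_from_spectrum(rnorm(10), fb), "match")
})

test_that("log-energy follows the analytic sum-of-squares law", {
  expect_equal(log_energy(rep(1, 256)), log(256))
  expect_equal(log_energy(rep(0, 256)), log(1e-10))
  x <- rnorm(256, sd = 100)
  expect_equal(log_energy(2 * x) - log_energy(x), log(4))
  expect_equal(log_energy(-x), log_energy(x))
})

test_that("first differences implement the three-case central rule", {
  expect_equal(first_differences(rep(3, 7)), rep(0, 7))
  expect_equal(first_differences(2 * (1:9)), rep(2, 9))  # slope preserved everywhere
  x <- c(5, 1, 4, 2, 9)
  want <- c(1 - 5, (4 - 5) / 2, (2 - 1) / 2, (9 - 4) / 2, 9 - 2)
  expect_equal(first_differences(x), want)
  m <- cbind(x, rev(x))  # reversing the sequence negates and reverses deltas
  expect_equal(first_differences(m), cbind(want, -rev(want)), ignore_attr = TRUE)
  expect_error(first_differences(1), "at least 2")
})

test_that("a 6-s block yields 515 x 26 features matching per-op composition", {
  set.seed(203)
  sig <- audio_signal(rnorm(6 * 11025, 0, 500), 11025)
  f <- extract_features(sig)
  expect_identical(dim(f), c(515L, 26L))
  # frame-by-frame composition of the individual operations
  frames <- frame_signal(sig)
  fb <- build_mel_filterbank(32, 256, 11025)
  static <- t(vapply(seq_len(nrow(frames)), function(i) {
    mag <- magnitude_spectrum(frames[i, ])
    c(mfcc_from_spectrum(mag, fb), log_energy(frames[i, ]))
  }, numeric(13)))
  want <- cbind(static, first_differences(static))
  expect_equal(unclass(f), want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pure silence gives constant MFCC columns and zero deltas", {
  f <- extract_features(audio_signal(rep(0, 11025), 11025))
  expect_true(all(apply(f[, 1:13], 2, function(c) max(c) - min(c)) == 0))
  expect_true(all(f[, 14:26] == 0))
  expect_equal(unname(f[1, 13]), log(1e-10))
})

test_that("shifting the input by one hop shifts the feature sequence by one frame", {
  set.seed(204)
  sig <- audio_signal(rnorm(4000, 0, 300), 11025)
  f1 <- extract_features(sig)
  f2 <- extract_features(audio_signal(sig$samples[-(1:128)], 11025))
  t2 <- nrow(f2)
  expect_equal(unclass(f2)[2:(t2 - 1), ], unclass(f1)[3:t2, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feature files round-trip through the columnar text format", {
  set.seed(205)
  f <- extract_features(audio_signal(rnorm(2000, 0, 300), 11025))
  path <- withr::local_tempfile(fileext = ".feat")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(unclass(back), unclass(f), tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(attr(back, "hop"), 128L)
  expect_identical(colnames(back), colnames(f))
})
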