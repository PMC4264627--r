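# Independent oracles and small fixture builders used across test files.

# Direct-sum orthonormal DCT-II of a vector (O(n^2) reference).
direct_dct2 <- function(v) {
  n <- length(v)
  m <- 0:(n - 1)
  vapply(0:(n - 1), function(k) {
    s <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    s * sum(v * cos(pi * k * (2 * m + 1) / (2 * n)))
  }, numeric(1))
}

# Naive O(n^2) DFT magnitude on the non-redundant half spectrum.
naive_dft_mag <- function(x) {
  n <- length(x)
  m <- 0:(n - 1)
  vapply(0:(n %/% 2), function(k) Mod(sum(x * exp(-2i * pi * k * m / n))),
         numeric(1))
}

# A random GMM-HMM with unit-mixture states, for decoder tests.
rand_hmm <- function(name, topo, n, d = 2, n_mix = 1) {
  states <- lapply(seq_len(n), function(s) {
    w <- stats::runif(n_mix); w <- w / sum(w)
    list(weights = w,
         means = matrix(stats::rnorm(n_mix * d, 0, 2), n_mix, d),
         vars = matrix(stats::runif(n_mix * d, 0.5, 2), n_mix, d))
  })
  mask <- coughmon:::topology_mask(topo, n)
  A <- matrix(0, n + 2, n + 2)
  for (i in seq_len(n + 1)) {
    w <- stats::runif(n + 2) * mask[i, ]
    A[i, ] <- w / sum(w)
  }
  coughmon:::new_sound_hmm(name, topo, states, log(A))
}

# Exhaustive path enumeration over a composite model's emitting states.
brute_force_decode <- function(model, B) {
  T <- nrow(B); n <- ncol(B)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  best <- -Inf; bp <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    sc <- model$log_entry[p[1]] + B[1, p[1]]
    if (T > 1) for (t in 2:T) sc <- sc + model$log_trans[p[t - 1], p[t]] + B[t, p[t]]
    if (sc > best) { best <- sc; bp <- unname(p) }
  }
  list(score = best, path = bp)
}

# A known 3-state left-to-right ground-truth model used in recovery tests.
truth_ltr3 <- function() {
  states <- list(
    list(weights = 1, means = matrix(c(0, 0), 1), vars = matrix(c(1, 1), 1)),
    list(weights = 1, means = matrix(c(4, -4), 1), vars = matrix(c(1, 1), 1)),
    list(weights = 1, means = matrix(c(-4, 4), 1), vars = matrix(c(1, 1), 1)))
  A <- matrix(0, 5, 5)
  A[1, 2] <- 1
  A[2, 2] <- 0.8; A[2, 3] <- 0.2
  A[3, 3] <- 0.7; A[3, 4] <- 0.3
  A[4, 4] <- 0.6; A[4, 5] <- 0.4
  coughmon:::new_sound_hmm("truth", "left_to_right", states, log(A))
}

# Small trained model suite shared by the heavier end-to-end tests; cached
# per session so training runs once.
trained_suite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- corpus_spec(seed = 303, n_cough_clips = 24,
                        n_background_blocks = 8, n_silence_blocks = 8)
    corpus <- make_corpus(spec, n_test_coughs = 6)
    ctl <- hmm_control(max_iterations = 12, seed = 17)
    models <- list(
      silence = train_sound_model(corpus$silence_blocks, "connected", 3, 3,
                                  ctl, name = "silence"),
      cough = train_sound_model(corpus$cough_clips[corpus$train_idx],
                                "left_to_right", 5, 5, ctl, name = "cough"),
      background = train_sound_model(corpus$background_blocks, "connected",
                                     4, 5, ctl, name = "background"))
    cache <<- list(spec = spec, corpus = corpus, control = ctl,
                   models = models, composite = build_composite(models))
    cache
  }
})
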