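# Parallel-grammar composite construction and token-passing decoding.

test_that("composite construction folds branches into a normalized block matrix", {
  set.seed(501)
  m <- build_composite(list(silence = rand_hmm("silence", "connected", 3),
                            cough = rand_hmm("cough", "left_to_right", 5),
                            background = rand_hmm("background", "connected", 6)))
  expect_identical(m$n_states, 14L)
  expect_identical(m$first_state, c(silence = 1L, cough = 4L, background = 9L))
  expect_identical(m$last_state, c(silence = 3L, cough = 8L, background = 14L))
  expect_identical(m$labels[4:8], rep("cough", 5))
  # rows over emitting states sum to 1 after folding the routing states
  expect_equal(rowSums(exp(m$log_trans)), rep(1, 14), tolerance = 1e-10)
  expect_equal(sum(exp(m$log_entry)), 1, tolerance = 1e-10)
  # per-branch entry mass matches the uniform grammar weights
  for (b in 1:3)
    expect_equal(sum(exp(m$log_entry)[m$labels == names(m$branches)[b]]),
                 1 / 3, tolerance = 1e-10)
  expect_error(build_composite(list(cough = rand_hmm("cough", "connected", 2))),
               "missing branch")
})

test_that("token passing equals exhaustive path enumeration on random instances", {
  set.seed(502)
  for (rep in 1:40) {
    n_sil <- sample(1:2, 1)
    n_coh <- sample(1:2, 1)
    if (n_sil + n_coh > 3) n_sil <- 1L   # keep the composite at <= 4 states
    m <- build_composite(list(
      silence = rand_hmm("silence", "connected", n_sil),
      cough = rand_hmm("cough", "left_to_right", n_coh),
      background = rand_hmm("background", "connected", 1)))
    stopifnot(m$n_states <= 4)
    T <- sample(2:6, 1)
    X <- matrix(rnorm(T * 2), T, 2)
    got <- viterbi_decode(X, m)
    want <- brute_force_decode(m, coughmon:::composite_emission(m, X))
    expect_equal(got$log_likelihood, want$score, tolerance = 1e-10)
    expect_identical(got$state_path, want$path)
    expect_identical(got$is_cough_block, any(m$labels[want$path] == "cough"))
  }
})

test_that("a single-branch composite decodes like the branch alone", {
  set.seed(503)
  hmm <- rand_hmm("cough", "left_to_right", 3, d = 2)
  m <- build_composite(list(cough = hmm), required = "cough")
  X <- matrix(rnorm(10), 5, 2)
  got <- viterbi_decode(X, m)
  want <- brute_force_decode(m, coughmon:::composite_emission(m, X))
  expect_equal(got$log_likelihood, want$score, tolerance = 1e-10)
  expect_identical(got$state_path, want$path)
  expect_true(got$is_cough_block)
})

test_that("symmetric degenerate composites break ties toward lower state indices", {
  st <- list(weights = 1, means = matrix(c(0, 0), 1), vars = matrix(c(1, 1), 1))
  states <- list(st, st, st)
  A <- matrix(0, 5, 5)
  A[1, 2:4] <- 1 / 3
  A[2:4, 2:5] <- 1 / 4
  hmm <- coughmon:::new_sound_hmm("background", "connected", states, log(A))
  m <- build_composite(list(background = hmm), required = "background")
  # folded matrix is exactly uniform: 1/4 within + 1/4 * 1/3 entry = 1/3
  expect_equal(exp(m$log_trans), matrix(1 / 3, 3, 3), tolerance = 1e-12)
  X <- matrix(rnorm(8), 4, 2)
  got <- viterbi_decode(X, m)
  expect_identical(got$state_path, rep(1L, 4))
  B <- coughmon:::composite_emission(m, X)
  expect_equal(got$log_likelihood, sum(B[, 1]) + 4 * log(1 / 3),
               tolerance = 1e-10)
})

test_that("cough traversal counting follows the last-state-to-first-state rule", {
  set.seed(504)
  m <- build_composite(list(silence = rand_hmm("silence", "connected", 1),
                            cough = rand_hmm("cough", "left_to_right", 2),
                            background = rand_hmm("background", "connected", 1)))
  # global indices: silence = 1, cough = 2..3 (last = 3), background = 4
  fake <- function(p) list(state_path = p)
  expect_identical(count_coughs(fake(c(2L, 3L, 1L, 2L, 3L, 4L)), m), 2L)
  expect_identical(count_coughs(fake(c(1L, 1L, 1L)), m), 0L)
  # enters the cough branch but never leaves through the final state
  expect_identical(count_coughs(fake(c(2L, 2L, 1L)), m), 0L)
  # ends in the final cough state with no following frame: not counted
  expect_identical(count_coughs(fake(c(1L, 2L, 3L)), m), 0L)
})

test_that("decoded event intervals are maximal indicator runs", {
  set.seed(505)
  # strongly separated 1-state branches so the path is predictable
  mk <- function(name, mu) {
    st <- list(weights = 1, means = matrix(c(mu, mu), 1),
               vars = matrix(c(1, 1), 1))
    A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 2] <- 0.9; A[2, 3] <- 0.1
    coughmon:::new_sound_hmm(name, "connected", list(st), log(A))
  }
  m <- build_composite(list(silence = mk("silence", 0),
                            cough = mk("cough", 10),
                            background = mk("background", -10)))
  X <- rbind(matrix(0, 3, 2), matrix(10, 2, 2), matrix(0, 2, 2),
             matrix(10, 3, 2))
  got <- viterbi_decode(X, m)
  expect_identical(got$cough_indicator, c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(got$cough_events$start_frame, c(4L, 8L))
  expect_identical(got$cough_events$end_frame, c(5L, 10L))
  expect_true(got$is_cough_block)
})

test_that("stream monitoring splits audio into abutting blocks and drops tails", {
  set.seed(506)
  m <- build_composite(list(silence = rand_hmm("silence", "connected", 1, d = 26),
                            cough = rand_hmm("cough", "left_to_right", 2, d = 26),
                            background = rand_hmm("background", "connected", 1, d = 26)))
  sig <- audio_signal(rnorm(13 * 11025, 0, 200), 11025)
  expect_message(mon <- monitor_stream(sig, m), "trailing partial block")
  expect_identical(length(mon$results), 2L)
  expect_identical(length(mon$results[[1]]$state_path), 515L)
  expect_equal(mon$block_start_s, c(0, 6))
  short <- audio_signal(rnorm(5.9 * 11025, 0, 200), 11025)
  expect_error(monitor_stream(short, m), "shorter than one")
})

test_that("restricting the cough branch to left-to-right never adds cough flags", {
  set.seed(507)
  # path-set inclusion: mask the connected cough branch's transitions to the
  # left-to-right subset without renormalizing; every surviving path existed
  # before with the same score, so flagged blocks cannot increase.
  con <- rand_hmm("cough", "connected", 3, d = 26)
  masked <- con
  mask <- coughmon:::topology_mask("left_to_right", 3)
  masked$log_trans[!mask] <- -Inf
  masked$topology <- "left_to_right"
  others <- list(silence = rand_hmm("silence", "connected", 2, d = 26),
                 background = rand_hmm("background", "connected", 2, d = 26))
  m_con <- build_composite(c(others, list(cough = con)))
  m_ltr <- build_composite(c(others, list(cough = masked)))
  flags <- function(m) {
    vapply(1:8, function(k) {
      set.seed(5070 + k)
      X <- matrix(rnorm(40 * 26), 40, 26)
      viterbi_decode(X, m)$is_cough_block
    }, logical(1))
  }
  expect_lte(sum(flags(m_ltr)), sum(flags(m_con)))
})

test_that("predict dispatches on clips, feature matrices and streams", {
  suite <- trained_suite()
  comp <- suite$composite
  clip <- suite$corpus$cough_clips[[length(suite$corpus$cough_clips)]]
  d1 <- predict(comp, clip)
  expect_s3_class(d1, "decode_result")
  d2 <- predict(comp, extract_features(clip))
  expect_identical(d1$state_path, d2$state_path)
  stream <- audio_signal(rep(suite$corpus$background_blocks[[1]]$samples, 2),
                         11025)
  mon <- predict(comp, stream)
  expect_s3_class(mon, "monitor_result")
  expect_identical(length(mon$results), 2L)
})
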