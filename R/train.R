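# Whole-model training: uniform-segmentation + k-means initialization,
# segmental Viterbi re-estimation, then Baum-Welch to convergence. All
# forward/backward arithmetic is carried out in the log domain; there is no
# linear-domain scaling path.

#' Training control parameters
#'
#' @param max_iterations iteration cap for each training pass.
#' @param tol convergence threshold: a pass stops when the total data
#'   log-likelihood improves by less than `tol` per frame.
#' @param variance_floor minimum variance per feature dimension, applied
#'   after every re-estimation.
#' @param trans_floor small probability floor applied to *allowed*
#'   transitions during the segmental pass only, so sparse Viterbi
#'   alignments cannot permanently zero out a permitted transition before
#'   Baum-Welch sees the data. Masked (topology-forbidden) transitions are
#'   never touched.
#' @param collapse_policy what to do when a mixture component receives no
#'   responsibility mass: `"reset"` keeps its previous parameters at a
#'   small floor weight; `"error"` aborts.
#' @param seed optional RNG seed consumed once at the start of
#'   [train_sound_model()] / [init_hmm()].
#' @return a list of class `hmm_control`.
#' @export
hmm_control <- function(max_iterations = 40L, tol = 1e-4, variance_floor = 1e-4,
                        trans_floor = 1e-4, collapse_policy = c("reset", "error"),
                        seed = NULL) {
  stopifnot(max_iterations >= 1L, tol > 0, variance_floor > 0, trans_floor >= 0)
  structure(list(max_iterations = as.integer(max_iterations), tol = tol,
                 variance_floor = variance_floor, trans_floor = trans_floor,
                 collapse_policy = match.arg(collapse_policy), seed = seed),
            class = "hmm_control")
}

as_feature_list <- function(sequences) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  lapply(sequences, function(X) {
    X <- unclass(X)
    attributes(X)[setdiff(names(attributes(X)), "dim")] <- NULL
    X
  })
}

uniform_log_trans <- function(topology, n_states, trans_floor = 0) {
  mask <- topology_mask(topology, n_states)
  A <- matrix(0, n_states + 2L, n_states + 2L)
  for (i in seq_len(n_states + 1L)) {
    k <- sum(mask[i, ])
    if (k > 0L) A[i, mask[i, ]] <- 1 / k
  }
  log(A)
}

# fit a J-component diagonal GMM to pooled frames by k-means
seed_state_gmm <- function(X, n_mix, variance_floor) {
  d <- ncol(X)
  pooled_var <- pmax(apply(X, 2L, stats::var), variance_floor)
  pooled_var[is.na(pooled_var)] <- variance_floor
  if (n_mix == 1L || nrow(unique(X)) < n_mix) {
    J <- 1L
    means <- matrix(colMeans(X), 1L, d)
    vars <- matrix(pooled_var, 1L, d)
    if (n_mix > 1L) {
      # not enough distinct frames for k-means: jitter copies of the mean
      means <- means[rep(1L, n_mix), , drop = FALSE] +
        matrix(stats::rnorm(n_mix * d, 0, sqrt(pooled_var) / 10),
               n_mix, d, byrow = FALSE)
      vars <- vars[rep(1L, n_mix), , drop = FALSE]
      J <- n_mix
    }
    return(list(weights = rep(1 / J, J), means = means, vars = vars))
  }
  km <- suppressWarnings(stats::kmeans(X, centers = n_mix, nstart = 3L,
                                       iter.max = 50L))
  means <- km$centers
  vars <- matrix(variance_floor, n_mix, d)
  weights <- numeric(n_mix)
  for (j in seq_len(n_mix)) {
    idx <- km$cluster == j
    weights[j] <- mean(idx)
    if (sum(idx) >= 2L) {
      vars[j, ] <- pmax(apply(X[idx, , drop = FALSE], 2L,
                              function(c) mean((c - mean(c))^2)), variance_floor)
    } else {
      vars[j, ] <- pmax(pooled_var, variance_floor)
    }
  }
  weights <- pmax(weights, 1e-3)
  list(weights = weights / sum(weights), means = means, vars = vars)
}

viterbi_core <- function(log_entry, logA, log_exit, B, use_exit = TRUE) {
  T <- nrow(B); n <- ncol(B)
  delta <- matrix(-Inf, T, n)
  psi <- matrix(0L, T, n)
  delta[1L, ] <- log_entry + B[1L, ]
  if (T > 1L) for (t in 2:T) {
    M <- delta[t - 1L, ] + logA          # M[i, j] = delta[i] + log a_ij
    best <- max.col(t(M), ties.method = "first")
    psi[t, ] <- best
    delta[t, ] <- M[cbind(best, seq_len(n))] + B[t, ]
  }
  final <- delta[T, ] + if (use_exit) log_exit else 0
  s <- which.max(final)
  if (!is.finite(final[s]))
    stop("no admissible state path (sequence shorter than the left-to-right ",
         "chain, or all paths have zero probability)")
  path <- integer(T)
  path[T] <- s
  if (T > 1L) for (t in (T - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  list(path = path, loglik = final[s])
}

#' Viterbi alignment of one feature sequence to a model
#'
#' Finds the single most likely state path through the model (entry and
#' exit dummy states included) and its log-likelihood.
#'
#' @param hmm a `sound_hmm`.
#' @param X feature matrix (one row per frame).
#' @return list with integer `path` (1-based emitting-state indices) and
#'   `loglik`.
#' @export
viterbi_align <- function(hmm, X) {
  n <- n_active_states(hmm)
  B <- emission_loglik(hmm, as_feature_list(X)[[1L]])
  viterbi_core(hmm$log_trans[1L, 2:(n + 1L)],
               hmm$log_trans[2:(n + 1L), 2:(n + 1L), drop = FALSE],
               hmm$log_trans[2:(n + 1L), n + 2L], B)
}

reestimate_from_alignment <- function(hmm, seqs, paths, control) {
  n <- n_active_states(hmm)
  d <- ncol(seqs[[1L]])
  mask <- is.finite(hmm$log_trans)
  counts <- matrix(0, n + 2L, n + 2L)
  frames_per_state <- vector("list", n)
  for (r in seq_along(seqs)) {
    p <- paths[[r]]
    counts[1L, p[1L] + 1L] <- counts[1L, p[1L] + 1L] + 1
    if (length(p) > 1L) for (t in seq_len(length(p) - 1L))
      counts[p[t] + 1L, p[t + 1L] + 1L] <- counts[p[t] + 1L, p[t + 1L] + 1L] + 1
    counts[p[length(p)] + 1L, n + 2L] <- counts[p[length(p)] + 1L, n + 2L] + 1
    for (s in unique(p))
      frames_per_state[[s]] <- c(frames_per_state[[s]],
                                 list(seqs[[r]][p == s, , drop = FALSE]))
  }
  A <- matrix(0, n + 2L, n + 2L)
  for (i in seq_len(n + 1L)) {
    row <- counts[i, ]
    row[!mask[i, ]] <- 0
    row[mask[i, ]] <- row[mask[i, ]] + control$trans_floor
    if (sum(row) > 0) A[i, ] <- row / sum(row)
    else A[i, mask[i, ]] <- 1 / sum(mask[i, ])
  }
  states <- hmm$states
  for (s in seq_len(n)) {
    if (is.null(frames_per_state[[s]])) next  # state never visited: keep params
    Xs <- do.call(rbind, frames_per_state[[s]])
    st <- states[[s]]
    J <- length(st$weights)
    if (J == 1L) {
      states[[s]]$weights <- 1
      states[[s]]$means <- matrix(colMeans(Xs), 1L, d)
      states[[s]]$vars <- matrix(pmax(colMeans(Xs^2) - colMeans(Xs)^2,
                                      control$variance_floor), 1L, d)
      next
    }
    Lc <- comp_loglik_matrix(Xs, st)
    assign <- max.col(Lc, ties.method = "first")
    w <- numeric(J)
    for (j in seq_len(J)) {
      idx <- assign == j
      nj <- sum(idx)
      w[j] <- nj
      if (nj >= 2L) {
        Xj <- Xs[idx, , drop = FALSE]
        states[[s]]$means[j, ] <- colMeans(Xj)
        states[[s]]$vars[j, ] <- pmax(colMeans(Xj^2) - colMeans(Xj)^2,
                                      control$variance_floor)
      } else if (nj == 0L && control$collapse_policy == "error") {
        stop("mixture component ", j, " of state ", s,
             " received no frames during segmental training")
      }
      # nj in {0, 1}: keep previous mean/var, floor the weight below
    }
    w <- pmax(w, 1e-3)
    states[[s]]$weights <- w / sum(w)
  }
  new_sound_hmm(hmm$name, hmm$topology, states, log(A), hmm$loglik_trace)
}

#' Initialize an HMM by segmental Viterbi training
#'
#' States are seeded by slicing every training sequence into `n_states`
#' equal-duration pieces; each state's mixture is seeded by k-means on the
#' pooled frames of its piece; transitions start uniform over the
#' topology's allowed successors. Viterbi alignment and re-estimation then
#' alternate until the total best-path log-likelihood gain drops below
#' `control$tol` per frame.
#'
#' @param sequences feature matrix or list of feature matrices.
#' @param topology `"connected"` or `"left_to_right"`.
#' @param n_states number of emitting states.
#' @param n_mix mixture components per state.
#' @param control an [hmm_control()].
#' @param name model label.
#' @return a `sound_hmm` with the segmental log-likelihood trace.
#' @export
init_hmm <- function(sequences, topology = c("connected", "left_to_right"),
                     n_states, n_mix = 1L, control = hmm_control(),
                     name = "sound") {
  topology <- match.arg(topology)
  seqs <- as_feature_list(sequences)
  if (length(seqs) == 0L) stop("empty training set")
  lens <- vapply(seqs, nrow, integer(1))
  if (topology == "left_to_right" && any(lens < n_states))
    stop("sequence of length ", min(lens), " cannot traverse a ",
         n_states, "-state left-to-right model")
  if (!is.null(control$seed)) set.seed(control$seed)
  d <- ncol(seqs[[1L]])

  # uniform-in-time segmentation, pooled across sequences
  pooled <- vector("list", n_states)
  for (X in seqs) {
    cuts <- floor(seq(0L, nrow(X), length.out = n_states + 1L))
    for (s in seq_len(n_states)) {
      rows <- (cuts[s] + 1L):max(cuts[s + 1L], cuts[s] + 1L)
      rows <- rows[rows <= nrow(X)]
      pooled[[s]] <- c(pooled[[s]], list(X[rows, , drop = FALSE]))
    }
  }
  states <- lapply(pooled, function(chunks)
    seed_state_gmm(do.call(rbind, chunks), n_mix, control$variance_floor))
  hmm <- new_sound_hmm(name, topology, states,
                       uniform_log_trans(topology, n_states))

  total_frames <- sum(lens)
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(control$max_iterations)) {
    ali <- lapply(seqs, function(X) viterbi_align(hmm, X))
    ll <- sum(vapply(ali, `[[`, numeric(1), "loglik"))
    trace <- c(trace, ll)
    hmm <- reestimate_from_alignment(hmm, seqs, lapply(ali, `[[`, "path"),
                                     control)
    if (is.finite(prev) && (ll - prev) < control$tol * total_frames) break
    prev <- ll
  }
  hmm$loglik_trace <- trace
  hmm
}

# forward-backward statistics for one sequence; returns accumulators
forward_backward <- function(hmm, X) {
  n <- n_active_states(hmm)
  T <- nrow(X)
  B <- emission_loglik(hmm, X)
  logA <- hmm$log_trans[2:(n + 1L), 2:(n + 1L), drop = FALSE]
  log_entry <- hmm$log_trans[1L, 2:(n + 1L)]
  log_exit <- hmm$log_trans[2:(n + 1L), n + 2L]

  la <- matrix(-Inf, T, n)
  la[1L, ] <- log_entry + B[1L, ]
  if (T > 1L) for (t in 2:T)
    la[t, ] <- B[t, ] + col_logsumexp(la[t - 1L, ] + logA)
  ll <- logsumexp(la[T, ] + log_exit)
  if (!is.finite(ll)) stop("sequence has zero probability under the model")

  lb <- matrix(-Inf, T, n)
  lb[T, ] <- log_exit
  if (T > 1L) for (t in (T - 1L):1L) {
    M <- logA + rep(B[t + 1L, ] + lb[t + 1L, ], each = n)
    lb[t, ] <- row_logsumexp(M)
  }
  gamma <- exp(la + lb - ll)

  xi_acc <- matrix(0, n, n)
  if (T > 1L) for (t in seq_len(T - 1L)) {
    M <- la[t, ] + logA
    M <- M + rep(B[t + 1L, ] + lb[t + 1L, ], each = n)
    xi_acc <- xi_acc + exp(M - ll)
  }
  list(loglik = ll, gamma = gamma, xi = xi_acc, B = B)
}

#' Baum-Welch re-estimation of a GMM-HMM
#'
#' Standard forward-backward expectation followed by re-estimation of
#' mixture weights, means, floored diagonal variances and transition
#' probabilities (entry and exit rows included), iterated until the total
#' data log-likelihood improves by less than `control$tol` per frame or
#' `control$max_iterations` is reached. Topology-forbidden transitions
#' stay at zero throughout. Components that receive essentially no
#' responsibility mass are handled per `control$collapse_policy`.
#'
#' @param hmm a `sound_hmm` (typically from [init_hmm()]).
#' @param sequences feature matrix or list of feature matrices.
#' @param control an [hmm_control()].
#' @return the re-estimated `sound_hmm`; its `loglik_trace` holds the
#'   per-iteration total log-likelihood (non-decreasing up to numerical
#'   slack).
#' @export
baum_welch <- function(hmm, sequences, control = hmm_control()) {
  seqs <- as_feature_list(sequences)
  if (length(seqs) == 0L) stop("empty training set")
  d <- ncol(seqs[[1L]])
  if (d != feature_dim(hmm)) stop("feature dimension mismatch")
  n <- n_active_states(hmm)
  mask <- is.finite(hmm$log_trans)
  total_frames <- sum(vapply(seqs, nrow, integer(1)))

  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(control$max_iterations)) {
    occ <- numeric(n)                      # total state occupancy
    entry_acc <- numeric(n)
    exit_acc <- numeric(n)
    xi_acc <- matrix(0, n, n)
    wt_acc <- lapply(hmm$states, function(s) numeric(length(s$weights)))
    mu_acc <- lapply(hmm$states, function(s) matrix(0, length(s$weights), d))
    sq_acc <- lapply(hmm$states, function(s) matrix(0, length(s$weights), d))
    ll_total <- 0

    for (X in seqs) {
      fb <- forward_backward(hmm, X)
      ll_total <- ll_total + fb$loglik
      occ <- occ + colSums(fb$gamma)
      entry_acc <- entry_acc + fb$gamma[1L, ]
      exit_acc <- exit_acc + fb$gamma[nrow(X), ]
      xi_acc <- xi_acc + fb$xi
      for (s in seq_len(n)) {
        st <- hmm$states[[s]]
        Lc <- comp_loglik_matrix(X, st)
        post <- exp(Lc - row_logsumexp(Lc)) * fb$gamma[, s]
        wt_acc[[s]] <- wt_acc[[s]] + colSums(post)
        mu_acc[[s]] <- mu_acc[[s]] + t(post) %*% X
        sq_acc[[s]] <- sq_acc[[s]] + t(post) %*% (X * X)
      }
    }
    trace <- c(trace, ll_total)

    # M-step: transitions
    A <- matrix(0, n + 2L, n + 2L)
    A[1L, 2:(n + 1L)] <- entry_acc / length(seqs)
    for (i in seq_len(n)) {
      den <- occ[i]
      if (den > 0) {
        A[i + 1L, 2:(n + 1L)] <- xi_acc[i, ] / den
        A[i + 1L, n + 2L] <- exit_acc[i] / den
      } else {
        A[i + 1L, ] <- exp(hmm$log_trans[i + 1L, ])
      }
    }
    A[!mask] <- 0
    rs <- rowSums(A)
    for (i in seq_len(n + 1L)) if (rs[i] > 0) A[i, ] <- A[i, ] / rs[i]

    # M-step: output distributions
    states <- hmm$states
    for (s in seq_len(n)) {
      w <- wt_acc[[s]]
      J <- length(w)
      dead <- w <= 1e-8
      if (any(dead) && control$collapse_policy == "error")
        stop("mixture component collapsed in state ", s)
      for (j in seq_len(J)) {
        if (dead[j]) next  # reset policy: keep previous parameters
        states[[s]]$means[j, ] <- mu_acc[[s]][j, ] / w[j]
        states[[s]]$vars[j, ] <- pmax(sq_acc[[s]][j, ] / w[j] -
                                        states[[s]]$means[j, ]^2,
                                      control$variance_floor)
      }
      wj <- w
      wj[dead] <- max(sum(w), 1) * 1e-3
      states[[s]]$weights <- wj / sum(wj)
    }
    hmm <- new_sound_hmm(hmm$name, hmm$topology, states, log(A), trace)
    if (is.finite(prev) && (ll_total - prev) < control$tol * total_frames) break
    prev <- ll_total
  }
  hmm$loglik_trace <- trace
  hmm
}

#' Fit a GMM-HMM sound model to a set of audio clips
#'
#' The main fitting entry point: extracts the 26-dimensional feature
#' sequence from every clip, initializes the model by segmental Viterbi
#' training and refines it by Baum-Welch re-estimation, mirroring the
#' whole-model HInit/HRest strategy of classic speech recognizers.
#' Canonical model orders for the three sound classes are: silence
#' connected 3 states x 3 mixtures; background connected with 3 or 6
#' states and 10-60 mixtures; cough 5 states and 10-60 mixtures, either
#' connected or left-to-right.
#'
#' @param clips list of [audio_signal()] clips (or feature matrices).
#' @param topology `"connected"` or `"left_to_right"`.
#' @param n_states number of emitting states.
#' @param n_mix mixture components per state.
#' @param control an [hmm_control()]; set `control$seed` for reproducible
#'   initialization.
#' @param config a [feature_config()].
#' @param name model label (e.g. `"cough"`, `"background"`, `"silence"`).
#' @return a fitted `sound_hmm`.
#' @examples
#' set.seed(7)
#' clips <- replicate(4, audio_signal(rnorm(6000, 0, 300)), simplify = FALSE)
#' m <- train_sound_model(clips, "connected", n_states = 2, n_mix = 2,
#'                        control = hmm_control(max_iterations = 3, seed = 1),
#'                        name = "background")
#' print(m)
#' @export
train_sound_model <- function(clips, topology = c("connected", "left_to_right"),
                              n_states, n_mix = 1L, control = hmm_control(),
                              config = feature_config(),
                              name = "sound") {
  topology <- match.arg(topology)
  if (length(clips) < 2L) stop("need at least 2 training clips")
  feats <- lapply(clips, function(cl)
    if (inherits(cl, "audio_signal")) extract_features(cl, config) else cl)
  hmm <- init_hmm(feats, topology, n_states, n_mix, control, name = name)
  baum_welch(hmm, feats, control)
}
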