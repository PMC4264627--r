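# Diagonal-covariance GMM-HMM containers and log-domain likelihoods.
#
# A `sound_hmm` follows the HTK state convention: the (n+2)x(n+2) log
# transition matrix includes a non-emitting entry state (row/col 1) and a
# non-emitting exit state (row/col n+2); rows 2..n+1 are the emitting
# states. The dummy states consume no time step. Masked transitions are
# stored as -Inf, which survives both training passes because masked
# transitions accumulate zero expected counts.

#' Numerically safe log-sum-exp
#'
#' `log(sum(exp(x)))` computed with the max shift so no intermediate
#' quantity underflows unless every term is `-Inf`.
#'
#' @param x numeric vector of log-domain terms.
#' @return a single value.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise / column-wise log-sum-exp of a matrix
row_logsumexp <- function(M) {
  m <- do.call(pmax, c(as.data.frame(M), na.rm = FALSE))
  m[!is.finite(m)] <- 0  # all--Inf rows: result is -Inf regardless of shift
  r <- m + log(rowSums(exp(M - m)))
  r
}
col_logsumexp <- function(M) row_logsumexp(t(M))

#' Log-density of one weighted diagonal Gaussian component
#'
#' Returns `log(alpha) - (M/2) log(2 pi) + (1/2) sum(log v) -
#' (1/2) sum(v (f - mu)^2)` where `v` holds the diagonal of the inverse
#' covariance. Computed entirely in the log domain so it never overflows
#' for finite inputs.
#'
#' @param f feature vector.
#' @param mean component mean vector.
#' @param var component variance vector (diagonal of the covariance).
#' @param weight mixture weight in (0, 1].
#' @return the log of the weighted density.
#' @export
log_gaussian_diag <- function(f, mean, var, weight = 1) {
  if (length(f) != length(mean) || length(f) != length(var))
    stop("dimension mismatch between feature vector and component parameters")
  if (any(var <= 0)) stop("non-positive variance entry")
  v <- 1 / var
  log(weight) - 0.5 * length(f) * log(2 * pi) + 0.5 * sum(log(v)) -
    0.5 * sum(v * (f - mean)^2)
}

#' Log-likelihood of a GMM state for one feature vector
#'
#' Sums the weighted component densities in the log domain with the
#' max-shifted log-sum-exp, so the result stays finite wherever the best
#' single component does even when a naive linear-domain sum would
#' underflow to zero.
#'
#' @param f feature vector.
#' @param state a state list with `weights`, `means` (J x d) and `vars`
#'   (J x d), as stored in a [train_sound_model()] fit.
#' @return the state log-likelihood `log sum_j alpha_j b_j(f)`.
#' @export
log_mixture_likelihood <- function(f, state) {
  J <- length(state$weights)
  if (J < 1L) stop("state has no mixture components")
  terms <- vapply(seq_len(J), function(j)
    log_gaussian_diag(f, state$means[j, ], state$vars[j, ], state$weights[j]),
    numeric(1))
  logsumexp(terms)
}

# T x J matrix of per-component weighted log-densities for all frames at once
comp_loglik_matrix <- function(X, state) {
  J <- length(state$weights)
  d <- ncol(X)
  out <- matrix(0, nrow(X), J)
  for (j in seq_len(J)) {
    v <- 1 / state$vars[j, ]
    Xc <- X - rep(state$means[j, ], each = nrow(X))
    out[, j] <- log(state$weights[j]) - 0.5 * d * log(2 * pi) +
      0.5 * sum(log(v)) - 0.5 * drop((Xc * Xc) %*% v)
  }
  out
}

# T x n_states emission log-likelihood matrix
emission_loglik <- function(hmm, X) {
  B <- matrix(0, nrow(X), length(hmm$states))
  for (s in seq_along(hmm$states))
    B[, s] <- row_logsumexp(comp_loglik_matrix(X, hmm$states[[s]]))
  B
}

topology_mask <- function(topology, n_states) {
  # logical (n+2)x(n+2) matrix of allowed transitions, HTK dummy convention
  n <- n_states
  A <- matrix(FALSE, n + 2L, n + 2L)
  if (topology == "left_to_right") {
    A[1L, 2L] <- TRUE                      # entry -> first emitting state
    for (i in seq_len(n)) {
      A[i + 1L, i + 1L] <- TRUE            # self loop
      A[i + 1L, i + 2L] <- TRUE            # advance (last state -> exit)
    }
  } else if (topology == "connected") {
    A[1L, 2L:(n + 1L)] <- TRUE             # entry -> any state
    A[2L:(n + 1L), 2L:(n + 2L)] <- TRUE    # any state -> any state or exit
  } else stop("unknown topology: ", topology)
  A
}

new_sound_hmm <- function(name, topology, states, log_trans,
                          loglik_trace = numeric(0)) {
  structure(list(name = name, topology = topology, states = states,
                 log_trans = log_trans, loglik_trace = loglik_trace),
            class = "sound_hmm")
}

n_active_states <- function(hmm) length(hmm$states)
feature_dim <- function(hmm) ncol(hmm$states[[1L]]$means)

#' @export
print.sound_hmm <- function(x, ...) {
  cat(sprintf("sound_hmm '%s': %d states (%s topology), %d mixture(s)/state, dim %d\n",
              x$name, n_active_states(x), x$topology,
              length(x$states[[1L]]$weights), feature_dim(x)))
  if (length(x$loglik_trace))
    cat(sprintf("  final training log-likelihood: %.4f (%d iterations)\n",
                x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace)))
  invisible(x)
}

#' @export
summary.sound_hmm <- function(object, ...) {
  n <- n_active_states(object)
  A <- exp(object$log_trans)
  cat(sprintf("GMM-HMM sound model '%s'\n", object$name))
  cat(sprintf("  topology: %s; active states: %d (+2 non-emitting dummies)\n",
              object$topology, n))
  cat(sprintf("  mixtures per state: %d; feature dimension: %d\n",
              length(object$states[[1L]]$weights), feature_dim(object)))
  cat("  self-loop probabilities:",
      paste(sprintf("%.3f", diag(A)[2:(n + 1L)]), collapse = " "), "\n")
  if (length(object$loglik_trace)) {
    cat(sprintf("  training log-likelihood trace (%d iterations):\n",
                length(object$loglik_trace)))
    print(zapsmall(object$loglik_trace, 4))
  }
  invisible(object)
}

#' @export
logLik.sound_hmm <- function(object, ...) {
  ll <- if (length(object$loglik_trace))
    object$loglik_trace[length(object$loglik_trace)] else NA_real_
  structure(ll, class = "logLik", df = hmm_n_parameters(object))
}

hmm_n_parameters <- function(hmm) {
  n <- n_active_states(hmm)
  J <- length(hmm$states[[1L]]$weights)
  d <- feature_dim(hmm)
  n_trans <- sum(is.finite(hmm$log_trans)) - 1L  # minus entry-row constraint
  n * (J * (2L * d) + (J - 1L)) + n_trans
}

#' Total data log-likelihood of sequences under a model
#'
#' Sum over sequences of the forward-algorithm log-likelihood (entry and
#' exit dummy states included).
#'
#' @param hmm a `sound_hmm`.
#' @param sequences a feature matrix or list of feature matrices.
#' @return total log-likelihood.
#' @export
hmm_loglik <- function(hmm, sequences) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  sum(vapply(sequences, function(X) forward_loglik(hmm, X), numeric(1)))
}

forward_loglik <- function(hmm, X) {
  n <- n_active_states(hmm)
  B <- emission_loglik(hmm, X)
  logA <- hmm$log_trans[2:(n + 1L), 2:(n + 1L), drop = FALSE]
  log_entry <- hmm$log_trans[1L, 2:(n + 1L)]
  log_exit <- hmm$log_trans[2:(n + 1L), n + 2L]
  alpha <- log_entry + B[1L, ]
  if (nrow(B) > 1L) for (t in 2:nrow(B))
    alpha <- B[t, ] + col_logsumexp(alpha + logA)
  logsumexp(alpha + log_exit)
}

#' Simulate feature sequences from a fitted sound model
#'
#' Samples state paths from the entry state until absorption in the exit
#' state, emitting one draw from the state's Gaussian mixture per time
#' step. Used for parameter-recovery checks and synthetic benchmarks.
#'
#' @param object a `sound_hmm`.
#' @param nsim number of sequences.
#' @param seed optional seed passed to [set.seed()].
#' @param max_len hard cap on sequence length (guards against models whose
#'   exit probability is tiny).
#' @param ... unused.
#' @return a list of `nsim` feature matrices with a `states` attribute
#'   holding the sampled state path of each.
#' @export
simulate.sound_hmm <- function(object, nsim = 1, seed = NULL, max_len = 10000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_active_states(object)
  A <- exp(object$log_trans)
  d <- feature_dim(object)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    path <- integer(0)
    s <- sample.int(n + 2L, 1L, prob = A[1L, ]) - 1L  # emitting index
    while (s <= n && length(path) < max_len) {
      path <- c(path, s)
      s <- sample.int(n + 2L, 1L, prob = A[s + 1L, ]) - 1L
    }
    X <- matrix(0, length(path), d)
    for (t in seq_along(path)) {
      st <- object$states[[path[t]]]
      j <- sample.int(length(st$weights), 1L, prob = st$weights)
      X[t, ] <- stats::rnorm(d, st$means[j, ], sqrt(st$vars[j, ]))
    }
    attr(X, "states") <- path
    out[[r]] <- X
  }
  out
}

#' Write a sound model to a JSON file
#'
#' The schema records the model name, topology, per-state mixture weights,
#' means and variances, and the full `(n+2) x (n+2)` transition matrix in
#' the linear domain (masked transitions as 0). Doubles are serialized at
#' full precision so [read_hmm()] round-trips the model bit-exactly.
#'
#' @param hmm a `sound_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  n <- n_active_states(hmm)
  obj <- list(
    format = "coughmon-hmm-1",
    name = hmm$name,
    topology = hmm$topology,
    n_states = n,
    feature_dim = feature_dim(hmm),
    # matrices stored flat in column-major order with explicit dimensions
    states = lapply(hmm$states, function(s)
      list(n_mix = length(s$weights), weights = s$weights,
           means = as.numeric(s$means), vars = as.numeric(s$vars))),
    trans = as.numeric(exp(hmm$log_trans)),
    loglik_trace = hmm$loglik_trace
  )
  # I(17) = 17 significant digits, enough to round-trip an IEEE double exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a sound model written by [write_hmm()]
#' @param path path to a model JSON file.
#' @return a `sound_hmm`.
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "coughmon-hmm-1"))
    stop("not a coughmon HMM model file: ", path)
  d <- as.integer(obj$feature_dim)
  n <- as.integer(obj$n_states)
  states <- lapply(obj$states, function(s) {
    J <- as.integer(s$n_mix)
    list(weights = as.numeric(unlist(s$weights)),
         means = matrix(as.numeric(unlist(s$means)), nrow = J, ncol = d),
         vars = matrix(as.numeric(unlist(s$vars)), nrow = J, ncol = d))
  })
  trans <- matrix(as.numeric(unlist(obj$trans)), n + 2L, n + 2L)
  new_sound_hmm(obj$name, obj$topology, states, log(trans),
                as.numeric(unlist(obj$loglik_trace)))
}
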