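# Parallel-grammar composite HMM and token-passing Viterbi decoding.
#
# The three class models are wired in parallel between shared non-emitting
# routing states: every branch exit routes to every branch entry, so the
# recognizer runs continuously. Because the routing states consume no time
# step they are folded into a single global transition matrix over emitting
# states before decoding.

#' Build a composite parallel-grammar HMM from class models
#'
#' The global transition matrix has a block structure: within-branch blocks
#' copy each model's transitions, and each branch's exit probability mass
#' is redistributed across all branch entries through the non-emitting
#' routing states, weighted by `entry_prob`. Rows over emitting states
#' therefore still sum to one.
#'
#' @param models named list of `sound_hmm` objects; must contain at least
#'   the names in `required` (default silence, cough, background).
#' @param entry_prob per-branch entry probabilities from the routing
#'   states; default uniform across branches.
#' @param required branch names that must be present.
#' @return an object of class `composite_hmm`.
#' @export
build_composite <- function(models, entry_prob = NULL,
                            required = c("silence", "cough", "background")) {
  missing_br <- setdiff(required, names(models))
  if (length(missing_br))
    stop("missing branch model(s): ", paste(missing_br, collapse = ", "))
  dims <- vapply(models, feature_dim, integer(1))
  if (length(unique(dims)) != 1L)
    stop("branch models disagree on feature dimension: ",
         paste(dims, collapse = ", "))
  nb <- length(models)
  if (is.null(entry_prob)) entry_prob <- rep(1 / nb, nb)
  if (length(entry_prob) != nb || abs(sum(entry_prob) - 1) > 1e-8)
    stop("entry_prob must give one probability per branch and sum to 1")

  sizes <- vapply(models, n_active_states, integer(1))
  offsets <- stats::setNames(cumsum(c(0L, sizes[-nb])), names(models))
  ntot <- sum(sizes)
  labels <- rep(names(models), sizes)
  within_index <- unlist(lapply(sizes, seq_len), use.names = FALSE)

  # per-branch pieces in the linear domain
  entry_rows <- lapply(models, function(m) {
    n <- n_active_states(m); exp(m$log_trans[1L, 2:(n + 1L)])
  })
  exit_cols <- lapply(models, function(m) {
    n <- n_active_states(m); exp(m$log_trans[2:(n + 1L), n + 2L])
  })

  # global initial distribution: branch weight times branch entry row
  pi0 <- unlist(mapply(function(w, e) w * e, entry_prob, entry_rows,
                       SIMPLIFY = FALSE), use.names = FALSE)
  # folded transition matrix
  P <- matrix(0, ntot, ntot)
  for (b in seq_len(nb)) {
    n <- sizes[b]
    idx <- offsets[b] + seq_len(n)
    P[idx, idx] <- exp(models[[b]]$log_trans[2:(n + 1L), 2:(n + 1L)])
    P[idx, ] <- P[idx, ] + exit_cols[[b]] %o% pi0
  }
  structure(list(branches = models,
                 entry_prob = entry_prob,
                 log_trans = log(P),
                 log_entry = log(pi0),
                 labels = labels,
                 within_index = within_index,
                 first_state = offsets + 1L,
                 last_state = offsets + sizes,
                 n_states = ntot),
            class = "composite_hmm")
}

#' @export
print.composite_hmm <- function(x, ...) {
  sizes <- vapply(x$branches, n_active_states, integer(1))
  cat(sprintf("composite_hmm: %d emitting states over %d branches (%s)\n",
              x$n_states, length(x$branches),
              paste(sprintf("%s:%d", names(x$branches), sizes), collapse = ", ")))
  invisible(x)
}

composite_emission <- function(model, X) {
  B <- matrix(0, nrow(X), model$n_states)
  g <- 0L
  for (b in seq_along(model$branches)) {
    hmm <- model$branches[[b]]
    B[, g + seq_len(n_active_states(hmm))] <- emission_loglik(hmm, X)
    g <- g + n_active_states(hmm)
  }
  B
}

#' Token-passing Viterbi decoding of a feature sequence
#'
#' Fills the `T x L` score lattice by the recursion
#' `s_j[n] = max_i(s_i[n-1] + log p_ij) + log B_j(f_n)`, keeping for every
#' state the best incoming token (ties broken toward the lower predecessor
#' state index), then backtraces from the best final token. The decoded
#' block is flagged as containing a cough exactly when the maximum
#' likelihood state path ever enters the cough branch.
#'
#' @param features feature matrix (`T x 26`), e.g. from
#'   [extract_features()].
#' @param model a [build_composite()] model.
#' @return an object of class `decode_result`: `state_path` (global state
#'   indices), `branch` (per-frame branch label), `cough_indicator` (0/1
#'   per frame), `log_likelihood`, `cough_events` (data frame of maximal
#'   indicator runs), `n_coughs` (traversal-count rule, see
#'   [count_coughs()]) and `is_cough_block`.
#' @export
viterbi_decode <- function(features, model) {
  stopifnot(inherits(model, "composite_hmm"))
  X <- as_feature_list(features)[[1L]]
  if (nrow(X) < 1L) stop("empty feature sequence")
  B <- composite_emission(model, X)
  dec <- viterbi_core(model$log_entry, model$log_trans,
                      log_exit = NULL, B, use_exit = FALSE)
  path <- dec$path
  ind <- as.integer(model$labels[path] == "cough")
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start_frame = starts[r$values == 1L],
                   end_frame = ends[r$values == 1L])
  res <- structure(list(state_path = path,
                        branch = model$labels[path],
                        cough_indicator = ind,
                        log_likelihood = dec$loglik,
                        cough_events = ev,
                        is_cough_block = any(ind == 1L)),
                   class = "decode_result")
  res$n_coughs <- count_coughs(res, model)
  res
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d frames, log-likelihood %.2f\n",
              length(x$state_path), x$log_likelihood))
  cat(sprintf("  cough block: %s; indicator runs: %d; counted coughs: %d\n",
              x$is_cough_block, nrow(x$cough_events), x$n_coughs))
  invisible(x)
}

#' Count complete cough traversals in a decoded path
#'
#' Counts the positions where the last state of the cough model is followed
#' by the first state of any model in the grammar, i.e. where a token left
#' the cough branch through its final emitting state.
#'
#' @param result a [viterbi_decode()] result.
#' @param model the `composite_hmm` it was decoded against.
#' @return integer count.
#' @export
count_coughs <- function(result, model) {
  path <- result$state_path
  T <- length(path)
  if (T < 2L) return(0L)
  last_cough <- model$last_state[which(names(model$branches) == "cough")]
  sum(path[-T] == last_cough & path[-1L] %in% model$first_state)
}

#' Decode a continuous audio stream in fixed blocks
#'
#' Partitions the signal into abutting `block_seconds` blocks (trailing
#' partial block dropped with a message), extracts features and runs
#' [viterbi_decode()] on each block.
#'
#' @param signal an [audio_signal()] at least one block long.
#' @param model a `composite_hmm`.
#' @param block_seconds block length in seconds (default 6).
#' @param config a [feature_config()].
#' @return an object of class `monitor_result`: per-block `results`, the
#'   per-block flags `is_cough_block`, block start times, and aggregate
#'   tallies `n_cough_blocks` and `n_coughs`.
#' @export
monitor_stream <- function(signal, model, block_seconds = 6,
                           config = feature_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  block_len <- as.integer(round(block_seconds * signal$sample_rate))
  n_blocks <- length(signal$samples) %/% block_len
  if (n_blocks < 1L)
    stop("signal (", sprintf("%.2f", audio_duration(signal)),
         " s) is shorter than one ", block_seconds, " s block")
  rem <- length(signal$samples) %% block_len
  if (rem > 0L)
    message("dropping trailing partial block of ", rem, " samples")
  results <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    block <- audio_signal(signal$samples[(k - 1L) * block_len + seq_len(block_len)],
                          signal$sample_rate)
    results[[k]] <- viterbi_decode(extract_features(block, config), model)
  }
  flags <- vapply(results, `[[`, logical(1), "is_cough_block")
  structure(list(results = results,
                 is_cough_block = flags,
                 block_start_s = (seq_len(n_blocks) - 1L) * block_seconds,
                 block_seconds = block_seconds,
                 n_cough_blocks = sum(flags),
                 n_coughs = sum(vapply(results, `[[`, integer(1), "n_coughs"))),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat(sprintf("monitor_result: %d blocks of %g s; %d flagged as cough; %d counted coughs\n",
              length(x$results), x$block_seconds, x$n_cough_blocks, x$n_coughs))
  invisible(x)
}

#' @describeIn build_composite decode audio or features against the model;
#'   returns a `decode_result` (for a clip/feature matrix) or a
#'   `monitor_result` (for a stream longer than one block).
#' @param object a `composite_hmm`.
#' @param newdata an [audio_signal()] or feature matrix.
#' @param config a [feature_config()] used when `newdata` is audio.
#' @param block_seconds block length used for long signals.
#' @param ... unused.
#' @export
predict.composite_hmm <- function(object, newdata, config = feature_config(),
                                  block_seconds = 6, ...) {
  if (inherits(newdata, "audio_signal")) {
    if (audio_duration(newdata) >= 2 * block_seconds)
      return(monitor_stream(newdata, object, block_seconds, config))
    return(viterbi_decode(extract_features(newdata, config), object))
  }
  viterbi_decode(newdata, object)
}
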