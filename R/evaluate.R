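# Holdout evaluation: sensitivity on withheld cough clips and false
# positives per hour on cough-free audio.

#' Classification counts for an evaluation run
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @param audited_hours hours of cough-free audio analyzed for the
#'   false-positive rate.
#' @return a list of class `eval_counts`.
#' @export
eval_counts <- function(tp = 0L, tn = 0L, fp = 0L, fn = 0L, audited_hours) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (audited_hours <= 0) stop("audited_hours must be positive")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 audited_hours = audited_hours),
            class = "eval_counts")
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`.
#'
#' @param counts an [eval_counts()], or a TP count if `fn` is given.
#' @param fn FN count when `counts` is a bare TP count.
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(counts, fn = NULL) {
  if (inherits(counts, "eval_counts")) {
    tp <- counts$tp; fneg <- counts$fn
  } else {
    tp <- counts; fneg <- fn
  }
  if (tp + fneg <= 0)
    stop("sensitivity is undefined: no positive examples (TP + FN = 0)")
  tp / (tp + fneg)
}

#' False positives per hour
#'
#' The number of false detections divided by the audited duration in
#' hours.
#'
#' @param fp_count false positive count (or an [eval_counts()]).
#' @param audited_hours hours of cough-free audio analyzed.
#' @return rate in events per hour.
#' @export
fp_per_hour <- function(fp_count, audited_hours = NULL) {
  if (inherits(fp_count, "eval_counts")) {
    audited_hours <- fp_count$audited_hours
    fp_count <- fp_count$fp
  }
  if (is.null(audited_hours) || audited_hours <= 0)
    stop("audited_hours must be positive")
  fp_count / audited_hours
}

signal_fingerprint <- function(sig) {
  paste(length(sig$samples), sum(sig$samples), sum(sig$samples^2), sep = "/")
}

#' Train and evaluate the full recognizer with a holdout protocol
#'
#' Trains the silence, background and cough models on the training clips,
#' builds the composite grammar model, then (a) decodes each withheld
#' cough clip -- a true positive iff the block is flagged as cough -- and
#' (b) decodes the cough-free audio in fixed blocks, counting every
#' flagged block as a false positive (the event-count variant from the
#' cough traversal rule is also reported). Train and test cough sets must
#' be disjoint.
#'
#' @param train_coughs,test_coughs lists of cough [audio_signal()] clips.
#' @param background_blocks,silence_blocks lists of 6-s training blocks.
#' @param cough_free an [audio_signal()] stream known to contain no coughs.
#' @param model_spec list with `s_bgr`, `mix_bgr`, `s_coh`, `mix_coh`,
#'   `top_coh` (`"connected"`/`"left_to_right"`), and optionally `s_sil`,
#'   `mix_sil` (default 3/3 connected).
#' @param control an [hmm_control()].
#' @param config a [feature_config()].
#' @param block_seconds evaluation block length (default 6).
#' @param models optional pre-trained named list (silence/cough/background)
#'   to reuse instead of training.
#' @param allow_overlap permit train/test overlap; a deliberate-leak sanity
#'   mode only, never a valid evaluation protocol.
#' @return a list of class `holdout_result` with the fitted `models`, the
#'   `composite`, an [eval_counts()], `sensitivity`, `fp_per_hour`
#'   (flagged-block rule), `fp_events_per_hour` (traversal-count rule) and
#'   a one-row `table_row` data frame mirroring the model-order experiment
#'   layout.
#' @export
run_holdout <- function(train_coughs, test_coughs, background_blocks,
                        silence_blocks, cough_free, model_spec,
                        control = hmm_control(), config = feature_config(),
                        block_seconds = 6, models = NULL,
                        allow_overlap = FALSE) {
  tr_ids <- vapply(train_coughs, signal_fingerprint, character(1))
  te_ids <- vapply(test_coughs, signal_fingerprint, character(1))
  if (!allow_overlap && any(te_ids %in% tr_ids))
    stop("protocol error: test cough clips overlap the training set")

  spec <- utils::modifyList(list(s_sil = 3L, mix_sil = 3L), model_spec)
  if (is.null(models)) {
    models <- list(
      silence = train_sound_model(silence_blocks, "connected",
                                  spec$s_sil, spec$mix_sil,
                                  control, config, name = "silence"),
      cough = train_sound_model(train_coughs, spec$top_coh,
                                spec$s_coh, spec$mix_coh,
                                control, config, name = "cough"),
      background = train_sound_model(background_blocks, "connected",
                                     spec$s_bgr, spec$mix_bgr,
                                     control, config, name = "background"))
  }
  composite <- build_composite(models)

  tp <- 0L
  for (clip in test_coughs) {
    dec <- viterbi_decode(extract_features(clip, config), composite)
    tp <- tp + as.integer(dec$is_cough_block)
  }
  fn <- length(test_coughs) - tp

  mon <- monitor_stream(cough_free, composite, block_seconds, config)
  fp <- mon$n_cough_blocks
  tn <- length(mon$results) - fp
  hours <- length(mon$results) * block_seconds / 3600
  counts <- eval_counts(tp = tp, tn = tn, fp = fp, fn = fn,
                        audited_hours = hours)
  row <- data.frame(S_BGR = spec$s_bgr, Mix_BGR = spec$mix_bgr,
                    S_COH = spec$s_coh, Mix_COH = spec$mix_coh,
                    Top_COH = if (spec$top_coh == "left_to_right") "LTR" else "CON",
                    FP_1h = fp_per_hour(counts),
                    R_TP = sensitivity(counts))
  structure(list(models = models, composite = composite, counts = counts,
                 sensitivity = sensitivity(counts),
                 fp_per_hour = fp_per_hour(counts),
                 fp_events_per_hour = mon$n_coughs / hours,
                 monitor = mon, table_row = row),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat("holdout_result\n")
  cat(sprintf("  sensitivity: %.3f (%d/%d held-out coughs)\n",
              x$sensitivity, x$counts$tp, x$counts$tp + x$counts$fn))
  cat(sprintf("  FP/1h (flagged blocks): %.3f over %.2f h; event-rule: %.3f\n",
              x$fp_per_hour, x$counts$audited_hours, x$fp_events_per_hour))
  print(x$table_row, row.names = FALSE)
  invisible(x)
}
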