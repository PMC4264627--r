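---
title: "Cough recognition with GMM-HMM acoustic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cough recognition with GMM-HMM acoustic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coughmon)
```

## The problem

Ambulatory cough monitoring asks a simple question of a continuous audio
stream: does this stretch of audio contain a cough? The audience is
digital-health monitoring — for example, objective symptom tallies for
asthma patients whose self-reports are unreliable. `coughmon` implements
the classic speech-recognition answer to that question: short-time
spectral features, per-class hidden Markov models with Gaussian-mixture
output densities, and maximum-likelihood (Viterbi) decoding against a
small grammar that runs the class models in parallel. Audio is judged in
fixed 6-second blocks; a block is flagged as containing a cough exactly
when the most likely state path passes through the cough model.

## Feature extraction

All analysis runs at a canonical sampling rate of 11025 Hz on mono
16-bit PCM audio. The chain, per frame, is:

1. **Framing.** 256-sample frames advancing by 128 samples (half-frame
   overlap), giving a frame period of 128/11025 ≈ 0.0116 s. Trailing
   samples that do not fill a whole frame are dropped; this is what makes
   a 6-s block yield exactly `floor((66150 − 256)/128) + 1 = 515` frames.
2. **Windowing and spectrum.** A symmetric 256-point Hann window
   (`0.5 − 0.5 cos(2πj/(n−1))`) multiplies the frame and the DFT magnitude
   is taken on the non-redundant half spectrum. No preemphasis filter is
   applied anywhere in the chain.
3. **Mel filterbank.** 32 triangular filters with centres equally spaced
   on the mel scale `mel(f) = 2595 log10(1 + f/700)` between 0 Hz and the
   Nyquist frequency, unit peak, applied to the *magnitude* (not power)
   spectrum. The filterbank geometry is a design choice: with only a
   published filterbank picture to go by, the standard 0-to-Nyquist
   equal-mel spacing is the closest defensible reading.
4. **MFCCs.** Natural logs of the 32 filterbank outputs (floored, see
   below) followed by a DCT-II, implemented through the even/odd
   index-reordering trick that computes a length-N DCT with a single
   length-N complex FFT. The test suite holds this path to the direct
   O(N²) cosine summation at 1e−10 relative tolerance. Coefficients 1–12
   are kept; coefficient 0 is computed and discarded because a separate
   time-domain energy measure is used. We adopt the *orthonormal* DCT-II
   scaling: any fixed scaling is self-consistent between training and
   decoding, so the choice only rescales features and is absorbed by the
   trained models.
5. **Log-energy.** `E = ln Σ x²[n]` over the raw integer-scale samples of
   the frame. Samples are deliberately *not* normalized to [−1, 1]: the
   energy feature is scale-dependent, so one convention must be fixed
   package-wide, and integer-domain energy matches the time-domain sample
   values as recorded.
6. **Deltas.** First differences `(f[i+1] − f[i−1])/2` at interior
   frames; at the sequence boundaries the difference between immediate
   neighbours. The final vector is 26-dimensional: 12 MFCCs, log-energy,
   and the 13 first differences.

**Log floor.** A frame of exact zeros (or an empty filterbank channel)
would produce `log(0)`. Both logs are floored at `ln(1e−10)`
(configurable via `feature_config(floor=)`), keeping every feature finite
without affecting non-degenerate audio. No cepstral liftering and no
cepstral mean normalization are applied.

## Sound models

Each sound class — `silence`, `background`, `cough` — is a hidden Markov
model whose states emit from diagonal-covariance Gaussian mixtures. The
transition matrix follows the HTK convention: a non-emitting entry state
and a non-emitting exit state surround the `n` active states, and the
dummy states consume no time step. Two topologies are supported:
*connected* (ergodic; any state to any state) and *left-to-right* (self
loop or advance only). Canonical orders are: silence 3 states × 3
mixtures (connected); background 3 or 6 states × 10–60 mixtures
(connected); cough 5 states × 10–60 mixtures in either topology. Where
model orders elsewhere are quoted dummy-inclusive, the active-state count
is that number minus two; this package counts active states everywhere.

All likelihood arithmetic is in the log domain. The per-state mixture
likelihood is computed by max-shifted log-sum-exp over the per-component
weighted log-densities, so 64-bit floats never underflow where the best
component is representable; the test suite exercises a case whose naive
linear-domain sum underflows to `−∞`. Forbidden transitions are stored as
`-Inf` in the log transition matrix — exact, stable under `exp`/`max`,
and preserved by training because masked transitions accumulate zero
expected counts.

## Training

`train_sound_model()` mirrors the whole-model HInit/HRest recipe:

- **Initialization (`init_hmm`).** Every sequence is sliced into
  `n_states` equal-duration pieces; the pooled frames of piece *s* seed
  state *s*'s mixture by k-means (`stats::kmeans`, seeded); transitions
  start uniform over the topology's allowed successors. Segmental
  (Viterbi) training then alternates best-path alignment with
  re-estimation until the total path log-likelihood gains less than `tol`
  per frame. All mixture components are created at once by k-means; no
  split-and-grow schedule is used, the simplest scheme consistent with
  whole-model training.
- **Baum-Welch (`baum_welch`).** Log-domain forward-backward with entry
  and exit rows re-estimated alongside the interior transitions, mixture
  responsibilities from per-component posteriors, and diagonal variances
  floored after every iteration. The per-iteration total log-likelihood
  trace is retained on the fitted object and is non-decreasing up to
  1e−6 numerical slack.

Convergence thresholds are not part of the original recipe, so the
package fixes conventional, documented defaults in `hmm_control()`:
`tol = 1e−4` log-likelihood per frame, `max_iterations = 40`,
`variance_floor = 1e−4`. Two guards deal with degenerate situations
explicitly rather than silently producing `NaN`: a mixture component
that receives no responsibility mass keeps its previous parameters at a
small floor weight (`collapse_policy = "reset"`; `"error"` aborts
instead), and during the *segmental pass only* a small floor
(`trans_floor = 1e−4`) is added to allowed transitions so a sparse
Viterbi alignment cannot permanently zero a permitted transition before
Baum-Welch ever sees the data — Baum-Welch itself is pure maximum
likelihood.

## The composite grammar and decoding

`build_composite()` wires the class models in parallel between shared
non-emitting routing states: every branch exit feeds every branch entry,
so the recognizer runs continuously. Because no published branch weights
exist for this grammar, entries are uniform across branches — the
simplest, freest combination. The routing states are folded away before
decoding: the global transition probability from state *i* to state *j*
is the within-branch transition plus (exit probability of *i*) × (branch
weight of *j*'s branch) × (entry probability of *j* within its branch).
Rows over emitting states therefore still sum to one, which the tests
check by direct summation.

`viterbi_decode()` is token-passing Viterbi: for each frame, propagate
every surviving token along allowed transitions, keep the best incoming
token per state (`s_j[n] = max_i(s_i[n−1] + log p_ij) + log B_j(f_n)`),
and backtrace from the best final token. Ties between equal incoming
tokens keep the lower predecessor state index — a deterministic,
documented choice. The decoder is held equal, path and score, to
exhaustive path enumeration on all random instances with ≤ 4 states and
≤ 6 frames.

Two cough statistics are reported per decoded block, because a flagged
block and a counted cough are different things:

- `is_cough_block`: the path entered the cough branch at all (the block
  classification rule);
- `n_coughs`: the number of positions where the *last* cough state is
  followed by the first state of any branch — complete traversals, the
  counting rule used for tallies. A path that enters the cough branch
  but never exits through its final state contributes to the first and
  not the second. The rule requires a following frame, so a traversal
  that ends exactly at the block boundary is not counted; event
  intervals (maximal runs of the cough indicator) are reported alongside
  for exactly this reason.

`monitor_stream()` cuts a stream into abutting, non-overlapping 6-s
blocks (block overlap is a design choice left open by the original
recipe; abutting blocks are the assumption here), dropping a trailing
partial block with a message.

## Evaluation

`run_holdout()` implements the holdout protocol: sensitivity
`TP/(TP+FN)` over withheld cough clips (per clip, not per event within a
clip), and false positives per hour over a cough-free stream. A false
positive is primarily a *flagged block*; the traversal-count variant is
reported as `fp_events_per_hour` since either reading of "false positive"
is defensible. Train/test disjointness is enforced by signal fingerprint;
an `allow_overlap` flag exists solely for deliberate-leak sanity checks.
The holdout split is by clip with a fixed seed; per-subject
cross-validation is impossible for synthetic data, which carries no
subject identity.

## The synthetic corpus

No public corpus of ambulatory cough audio accompanies this package, so
`make_corpus()` generates one with the same *structure*: variable-length
isolated cough clips (0.2–0.8 s), fixed 6-s background and silence
blocks, and continuous streams with sample-accurate ground-truth event
intervals. The acoustics are deliberately simple:

- **cough** — a two-phase transient: ~3 ms attack, fast exponential
  decay, a weaker second burst at 45% of the duration, carried by noise
  band-emphasized at 0.8–3.2 kHz (a `signal::butter` bandpass). Peak
  amplitudes 5000–12000 on the 16-bit scale.
- **background** — stationary low-passed colored noise with slow
  (0.1–0.5 Hz) sinusoidal amplitude modulation, RMS 400.
- **silence** — white noise at RMS 8, i.e. > 20 dB below background.

Defaults mirror the emulated study's scale where desk-feasible: 140
cough clips (110 train / 30 held out), 20 background and 20 silence
blocks, and cough-free audio generated on demand (20 minutes in the
acceptance script — far less than a field corpus of many hours, a
deliberate desk-scale choice). Streams embed coughs at 20 dB above the
background RMS by default: clearly audible events, the regime the
block-level protocol is about.

The generator's goal is *statistical separability*, not clinical
realism. It contains no reverberation or room acoustics, no speaker or
disease variability, no confusable transients (speech plosives, door
slams, throat clears), and its "cough" is a stylized envelope rather
than a physiological model. Consequently, passing the end-to-end tests
demonstrates that the machinery — features, training, grammar, decoding,
metrics — is correct and self-consistent; it does not certify field
performance on real recordings, where false-alarm rates are driven
precisely by the confusable sounds this generator omits. Absolute
published benchmark numbers from real corpora are therefore out of scope
here; only the qualitative topology trend is asserted (below).

## Numerical and design choices at a glance

- Orthonormal DCT-II; reordered-FFT implementation tested against the
  direct summation at 1e−10.
- Log floor `1e−10` for filterbank outputs and frame energy.
- Symmetric Hann window (n−1 denominator).
- `-Inf` log transitions for topology masks; `trans_floor` only in the
  segmental pass.
- Variance floor `1e−4` after every re-estimation.
- Viterbi ties → lower predecessor state index.
- Uniform branch entry probabilities in the grammar.
- Abutting 6-s blocks; trailing partial blocks dropped.
- Frame indices are 0-based in time bookkeeping (frame *i* starts at
  sample *i*·hop); R-side vectors are 1-based as usual.

## Problem sizes used by the test and acceptance runs

The heavier checks train real models, so their corpus sizes are chosen
for a single-CPU desk run: the in-suite benchmark uses 60 cough clips
(45/15 split), 10 background and 10 silence blocks, 10 mixtures per
state, a 15-iteration cap, and 6 minutes of cough-free audio; the
acceptance script scales up to the full default corpus (110/30 coughs,
20/20 blocks, 20 minutes cough-free). Parameter recovery uses 200
sequences simulated from a known 3-state left-to-right model and checks
self-loop probabilities to ±0.05 and state means to 3 standard errors.

## Known limitations

- The recognizer has no tunable decision threshold: the block decision
  is the argmax path, so there is no ROC curve to sweep.
- Decoding is whole-block batch Viterbi; no beam pruning, no bounded
  latency, no streaming token passing.
- Single-channel 11025 Hz input only; other rates are accepted with a
  warning but never resampled.
- Synthetic-corpus caveats above: separability on this corpus is a
  correctness bar, not a field-performance claim.

```{r example, eval = FALSE}
# end-to-end sketch
spec <- corpus_spec(seed = 1)
corpus <- make_corpus(spec)
ctl <- hmm_control(max_iterations = 15, seed = 2)
models <- list(
  silence    = train_sound_model(corpus$silence_blocks, "connected", 3, 3,
                                 ctl, name = "silence"),
  background = train_sound_model(corpus$background_blocks, "connected", 6, 10,
                                 ctl, name = "background"),
  cough      = train_sound_model(corpus$cough_clips[corpus$train_idx],
                                 "left_to_right", 5, 10, ctl, name = "cough"))
composite <- build_composite(models)
stream <- make_labeled_stream(spec, n_events = 12, minutes = 2)
monitor_stream(stream$signal, composite)
```
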