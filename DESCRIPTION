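Package: coughmon
Title: Cough Detection in Continuous Audio with GMM-HMM Acoustic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A frame-based cough recognition engine for continuous ambulatory
    audio monitoring. Extracts 26-dimensional mel-frequency cepstral
    coefficient (MFCC) and log-energy feature vectors from mono 16-bit PCM
    audio, fits diagonal-covariance Gaussian-mixture hidden Markov models
    (GMM-HMMs) for cough, background and silence sound classes by segmental
    Viterbi initialization and Baum-Welch re-estimation, joins the class
    models into a composite parallel-grammar HMM, and decodes audio streams
    by token-passing Viterbi to flag 6-second blocks that contain coughs.
    Includes a seeded synthetic corpus generator, holdout evaluation with
    sensitivity and false-positives-per-hour metrics, and model-order
    experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
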