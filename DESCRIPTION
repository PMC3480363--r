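Package: basm
Title: Brain-Computer-Interface Attention Scoring and Neurofeedback Trial Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-channel frontal-EEG (Fp1/Fp2) attention-training
    pipeline: synthetic EEG generation with state-dependent spectra and
    artifacts, screening of saturated and disconnected segments, filter-bank
    band-power feature extraction over 2-second blocks with a virtual
    differential channel, mutual-information feature selection and a ridge
    regression calibrated into a 0-100 attention display score, a closed-loop
    training-session simulator, and clinical-trial outcome statistics
    (ADHD rating-scale scoring, last-observation-carried-forward imputation,
    paired change tests, baseline-predicts-change regression and Spearman
    correlations between score changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
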