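Package: speechnpi
Type: Package
Title: Paralinguistic Speech Markers of Neuropsychiatric Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts paralinguistic markers (temporal, prosodic, formant,
    source and spectral feature families) from short narrative speech
    recordings and relates them to Neuropsychiatric Inventory (NPI) apathy,
    depression and anxiety subscale scores. Provides energy-based voice
    activity detection, autocorrelation pitch tracking, cycle-level jitter,
    shimmer and harmonics-to-noise estimation, linear-prediction formant
    tracking and mel-frequency cepstral coefficients; gender- and
    task-stratified Spearman and MMSE-partial Spearman correlations with
    per-category Benjamini-Hochberg false-discovery control; and
    leave-one-out cross-validated support-vector and Lasso regression of
    subscale scores against a mean-predictor baseline. A source-filter voice
    synthesizer and cohort simulator with planted feature-symptom effects
    make every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
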