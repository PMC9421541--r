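Package: microspect
Title: Frequency-Specific EEG Microstate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates
    by polarity-invariant modified k-means clustering of global field power
    peak topographies, backfitting of grand-mean maps with temporal smoothing
    and minimum-duration rules, computation of per-map temporal measures
    (occurrence, mean duration, time coverage) within canonical frequency
    bands, group comparison by permutation tests with Bonferroni correction
    and Cohen's d, and microstate-based classification with ReliefF feature
    ranking and linear support vector machines under repeated stratified
    cross-validation. Includes a synthetic two-group EEG generator with known
    microstate templates and dynamics for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
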