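Package: semgcobb
Title: Cobb Angle Outcome Prediction from Surface Electromyography in
    Adolescent Idiopathic Scoliosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting Cobb angle and related clinical outcomes in
    adolescent idiopathic scoliosis patients undergoing Schroth exercise
    therapy from multichannel surface electromyography (sEMG). Implements
    Butterworth band-pass signal conditioning, root-mean-square (RMS) and
    paraspinal muscle symmetry index (PMSI) feature extraction, a dual-branch
    TCN-LSTM regression model with TCN, LSTM and support-vector-regression
    baselines, grouped cross-validation benchmarking, and a synthetic-cohort
    generator calibrated to published cohort statistics so the full pipeline
    can be exercised end to end without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
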