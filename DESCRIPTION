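Package: erpdecode
Title: Moving-Window Multivariate Decoding of Epoched EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sliding-window multivariate pattern analysis of epoched EEG.
    Implements per-participant linear support-vector classification of
    binary choices and support-vector regression of continuous ratings in
    consecutive 10-ms analysis windows, with shuffled-label empirical null
    runs, one-tailed paired group tests, cluster-mass permutation
    correction across windows, and feature-weight channel topographies.
    Ships a synthetic epoched-EEG and behavior generator (spatially
    correlated pink noise with latent-appeal-driven signal injection) so
    every stage is testable end to end without recorded data, plus
    preprocessing (baseline subtraction, amplitude-based epoch rejection),
    a lossless epoch container format, behavioral descriptives/ANOVA
    utilities, and a JSON-configured pipeline with a thin command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
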