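Package: landlrp
Title: Explainable Classification of Landing Waveforms with Layer-Wise
    Relevance Propagation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recognising lower-limb landing patterns from
    time-normalised joint-angle and joint-moment waveforms and for explaining
    the classifier's decisions. Provides a synthetic two-class (pre- versus
    post-fatigue) waveform generator with subject random effects and
    phase-localised class differences, nine channel-subset classification
    tasks with subject-grouped eight-fold cross-validation and a Zero-R
    baseline, a transparent feed-forward network classifier, layer-wise
    relevance propagation (z-rule) onto the input grid, relevance
    post-processing (averaging, 25/50/25 smoothing, [0,1] scaling,
    contribution aggregation, high-relevance extraction), and statistical
    evaluation via one-dimensional statistical parametric mapping
    (paired-t trajectories with random-field-theory thresholds, sign-flip
    permutation cross-check, and Rosenthal t-to-r effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
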