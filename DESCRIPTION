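Package: numopop
Title: Population Analysis of Numerosity Coding During Sensorimotor
    Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-neuron spike data from a
    number production task in which numerical instruction cues (1-5, dot
    arrays or numeral signs) are transformed into a matching count of
    self-generated actions. Provides a Poisson spike-train simulator with
    known ground-truth tuning and Weber-law behavior, a plain-text dataset
    format, behavioral performance metrics, sliding-window two-factor ANOVA
    selectivity analysis with split-half reliability, resampled linear SVM
    population decoding (within/across format, cross-phase, error-trial and
    outcome decoding), omega-squared percent-explained-variance time
    courses, cross-temporal decoding matrices, and cluster-based
    permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
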