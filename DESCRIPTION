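Package: gazehmm
Title: Hidden Markov Model Analysis of Eye Movements in Face Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Person-specific hidden Markov models of fixation sequences with
    Gaussian regions of interest, fitted by variational Bayesian EM with
    automatic selection of the number of ROIs; clustering of individual models
    into representative gaze patterns by hierarchical EM over virtual samples;
    likelihood-based pattern quantification on the A-B scale; marginal and
    conditional fixation-entropy consistency measures; signal-detection
    performance summaries (d-prime, criterion, response time) with
    within-subject factorial contrasts, correlation and partial-correlation
    analyses, and regression power analysis; and a synthetic-experiment
    generator that emulates a 2x2 masked-face recognition design with planted
    individual-difference couplings, so the full pipeline can be exercised
    end to end against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
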