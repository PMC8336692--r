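Package: aestheticfmri
Title: Agreement, Taste Decomposition, Motion Energy and ROI-Level fMRI
    Statistics for Naturalistic Aesthetic Rating Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing naturalistic aesthetic-rating fMRI
    experiments in which participants watch short video clips while giving
    continuous enjoyment ratings and an overall aesthetic judgment per clip.
    Implements mean-minus-one (MM1) inter-rater agreement for overall and
    continuous ratings, a variance decomposition of repeatable rating
    variance into shared and individual taste, Gabor-jet motion energy of
    frame stacks, appeal-level general linear models on ROI-averaged BOLD
    timeseries with canonical HRF regressors and group contrast tests,
    trial-wise functional connectivity with appeal regression and edge-wise
    FDR, and time-resolved connectivity via multiplication of temporal
    derivatives (MTD). A synthetic-data generator with known ground truth
    emulates the full study design so every stage is testable without
    access to raw participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
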