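Package: prognet
Title: Bayesian-Network Prognosis Modelling with Phantom Image Segmentation and RECIST Efficacy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Max-min hill-climbing (MMHC) structure learning for discrete
    Bayesian networks applied to survival-status prognosis in advanced
    non-small-cell lung cancer, together with the surrounding analysis
    pipeline: chi-square and logistic-regression feature screening,
    equidistant discretization, exact posterior inference by enumeration,
    CT-phantom lesion segmentation with a from-scratch backpropagation pixel
    classifier (Wiener denoising, fuzzy contrast enhancement, co-occurrence
    texture and differential box-counting fractal features), lesion diameter
    and volume measurement, RECIST response classification with objective
    response and disease control rates, and Kaplan-Meier progression-free
    survival. A synthetic-data generator provides cohorts from a known
    ground-truth network, lesion phantoms with known geometry, and two-arm
    follow-up times, so every stage is testable against a recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
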