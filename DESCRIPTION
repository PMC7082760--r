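Package: dlvmcf
Title: Deep Latent Variable Models for Counterfactual Inference on Ordinal
    Tumor Grades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers personalized causal effects of binary genomic
    aberrations (gene fusions, somatic and germline mutations, copy number
    alterations) on an ordinal clinical outcome such as the Gleason Score,
    from noisy discrete and continuous proxy features. The core model is a
    pair of variational autoencoders over discrete (Bernoulli) and
    continuous (Gaussian) latent confounders joined through a shared
    confounder layer, trained by stochastic gradient ascent on an evidence
    lower bound and able to reconstruct factual outcomes and estimate
    counterfactual ones. Includes the individual causal effect (ICE),
    average ICE (AICE) and factual-reconstruction RMSE estimands, a
    replicated stratified cross-validation experiment driver with paired
    t-test group comparisons, a multilayer-perceptron race-label imputer,
    a genomic-risk-score mapping, and a synthetic cohort generator with
    known potential outcomes for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
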