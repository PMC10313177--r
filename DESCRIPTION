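Package: tnbcqsp
Title: Quantitative Systems Pharmacology Virtual Trials for Metastatic
    Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A mechanistic nine-compartment ordinary-differential-equation
    model of tumour-immune-drug dynamics in metastatic triple-negative
    breast cancer, with a virtual-clinical-trial engine for pembrolizumab
    monotherapy. Virtual patients are generated by Latin hypercube sampling
    with stochastic metastatic seeding and a pre-treatment burn-in;
    responses are scored by RECIST v1.1. Includes a biomarker-discovery
    framework (response probability, responder inclusion score, clonal and
    T-cell diversity indices, single and paired biomarker ranking with
    bootstrap confidence intervals), parameter-sensitivity analyses, and
    calibration utilities for immune-cell abundance in metastases and
    trial-level targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
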