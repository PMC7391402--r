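Package: proirt
Title: Integrated Item Response Theory Modeling of Patient-Reported
    Outcomes in BPH-LUTS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacometric item response theory (IRT) analysis of
    patient-reported outcomes for lower urinary tract symptoms associated
    with benign prostatic hyperplasia (BPH-LUTS).  Implements graded
    response models (unidimensional and compensatory multidimensional)
    for item-level IPSS, QoL and summary BPH Impact Index data, pooled
    item-characteristic-curve estimation by marginal maximum likelihood,
    Fisher-information ranking of items, latent-disability trajectory
    models with placebo, drug and covariate effects fitted by Laplace
    approximation, stepwise covariate modeling, clinical-trial simulation,
    categorical visual predictive checks, and power analysis by stochastic
    simulation and estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    mvtnorm,
    TMB,
    tools,
    yaml
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
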