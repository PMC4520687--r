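Package: thiodose
Title: Bayesian Individualized 6-Mercaptopurine Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based individualization of 6-mercaptopurine (6-MP) therapy
    through the active metabolite 6-thioguanine nucleotide (6-TGN). Provides a
    three-state mechanistic model of 6-MP absorption, clearance and
    TPMT-modulated conversion to 6-TGN; per-patient maximum-likelihood and
    Bayesian estimation (Metropolis-Hastings MCMC and a Gaussian variational
    approximation); pooled population and TPMT-activity-group priors; Sobol
    total-sensitivity model reduction with a probabilistic fixing-error bound;
    robust D-optimal selection of the blood-sampling day; robust
    model-predictive dose control toward the therapeutic 6-TGN window; and a
    virtual-patient generator emulating sparse clinical datasets so the whole
    chain is testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    lhs,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
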