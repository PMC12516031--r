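Package: hcmdce
Title: Hybrid Choice Models for Discrete Choice Experiments on Inclusive Health Insurance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for stated-preference studies of
    complementary inclusive ("Huimin"-type) health insurance: D-efficient
    blocked discrete choice experiment designs with a dominance-based
    quality-control task, synthetic survey generation under an integrated
    choice and latent variable (ICLV) data-generating process, scale
    reliability diagnostics (Cronbach's alpha, composite reliability,
    average variance extracted), and joint simulated-maximum-likelihood
    estimation of the hybrid choice model (structural and ordered-logit
    measurement components plus a panel mixed logit with an opt-out
    alternative) with scrambled Halton draws, robust sandwich standard
    errors, and willingness-to-pay post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    pracma,
    MASS,
    optparse
Config/testthat/edition: 3
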