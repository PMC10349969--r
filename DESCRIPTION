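Package: madfe
Title: Distributions of Mutational Effects from Microcolony Growth Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage inference of the distribution of mutational effects
    (DFE/DME) on growth rate from mutation-accumulation (MA) line microcolony
    data. Stage one estimates per-strain selection coefficients and petite
    (respiration-deficient) subpopulation proportions from colony growth rates
    via a batch-effect-cancelling pairwise-difference Gaussian-mixture
    likelihood with profile-likelihood standard errors and FDR-controlled
    significance calls. Stage two fits compound-Poisson reflected-gamma models
    of single-mutation effects (with alternative treatments of unidentified
    mutations) by characteristic functions and inverse FFT, with
    profile-likelihood confidence intervals, AIC and likelihood-ratio model
    comparison, and closed-form tail-mass summaries. Includes a synthetic-data
    generator reproducing the assay's plate/well/colony noise structure so the
    whole pipeline is testable without raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
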