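Package: abnma
Title: Arm-Based and Contrast-Based Bayesian Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian network meta-analysis (NMA) of arm-level binary outcome
    data under an exact binomial likelihood, implementing a ladder of four
    structural models that differ in how study intercepts are treated: the
    Lu-Ades contrast-based model with fixed intercepts, a contrast-based model
    describing all possible arms (with an equivalent arm-based form), a
    contrast-based model with random study intercepts, and the Hong-style
    arm-based model in which random study intercepts may be correlated with
    treatment effects.  Supports common and non-common heterogeneity
    covariance structures (including a compound-symmetry structure for the
    arm-based model), evidence-based lognormal heterogeneity priors matched
    across models, conditional and marginal estimands, deterministic
    hypothetical-data generators for studying between-study information and
    missing-data bias, and a packaged inhaled-corticosteroids example network.
    Posterior sampling uses JAGS via 'rjags'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
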