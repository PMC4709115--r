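Package: adaptiveMK
Title: Maximum-Likelihood McDonald-Kreitman Estimation of the Adaptive
    Amino-Acid Substitution Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the distribution of fitness effects (DFE) of
    non-synonymous mutations from synonymous and non-synonymous site
    frequency spectra together with divergence counts, in a Poisson
    maximum-likelihood framework with per-frequency-class nuisance
    parameters absorbing demography and orientation errors. From a fitted
    model the package derives the non-adaptive substitution rate omega_na,
    the adaptive rate omega_a and the proportion of adaptive amino-acid
    substitutions alpha, with likelihood-ratio tests, AIC model comparison
    and profile-likelihood confidence intervals. Includes SFS construction
    utilities (outgroup-based orientation, hypergeometric projection,
    folding), a Poisson simulator for validation, and a small comparative
    layer for cross-species regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectra.R'
    'dfe.R'
    'expectations.R'
    'inference.R'
    'adaptiveRate.R'
    'simulate.R'
    'meta.R'
    'cli.R'
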