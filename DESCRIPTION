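Package: growsel
Title: Growth-Curve Fitting and Genetic-Hypothesis Selection for Seedling
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits expolinear, Gompertz and sigmoidal decay growth curves to
    longitudinal seedling trait data by maximum-likelihood generalized
    non-linear least squares with first-order autoregressive (AR1)
    within-plant correlation and heteroskedastic variance functions
    (exponential-of-time or per-harvest strata).  Compares five genetic
    grouping hypotheses for a two-parent reciprocal-hybrid design (full
    genotype, nuclear genotype, maternal seed-size class, parental-vs-hybrid,
    uniform) by small-sample Akaike information criteria with Akaike weights
    and evidence ratios.  Includes end-point trait comparison with Tukey HSD
    compact letter displays, seed shape descriptors, derived resource
    allocation statistics, and a synthetic-data generator that emulates
    repeated non-destructive root/shoot measurements and destructive dry
    weight harvests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
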