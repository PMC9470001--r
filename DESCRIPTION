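Package: adaptwalk
Title: Adaptive and Nonadaptive Protein Substitution Rates Across Gene Age Strata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of adaptive (omega_a) and nonadaptive (omega_na)
    nonsynonymous substitution rates from polymorphism and divergence data,
    stratified by gene age. Fits a Gamma-Exponential distribution of fitness
    effects to paired synonymous/nonsynonymous unfolded site frequency
    spectra by Poisson random field maximum likelihood, with gene-level
    bootstrap confidence intervals. Includes phylostratum merging schemes,
    cofactor high/low splits and filters, a Grantham physicochemical
    distance analysis of substitution effect sizes (site-weighted mean
    distances of adaptive and nonadaptive substitutions), the statistical
    machinery used to compare strata (bootstrap sign tests, Kendall
    correlation on category means, FDR, weighted-Z combination, nested
    ANCOVA, Cox-Snell pseudo-R2), and a synthetic-data generator emulating
    stratum-dependent selection regimes so the whole pipeline can be
    validated without genome-scale data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
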