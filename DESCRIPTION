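Package: heatmargin
Title: Phylogenetic Imputation of Heat Tolerance and Overheating Risk in
    Ectotherm Assemblages
Version: 0.1.0
Authors@R:
    person("heatmargin", "developers", email = "heatmargin@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the vulnerability of ectotherm (amphibian)
    assemblages to extreme heat. Implements Bayesian augmentation with
    chained equations (BACE) for phylogenetic imputation of critical
    thermal maxima from sparse laboratory compilations, inverse-variance
    weighted estimation of acclimatization response ratios, daily
    plasticity-adjusted thermal limits, warmest-quarter exposure
    bookkeeping, and three overheating metrics (thermal safety margins,
    expected overheating-day counts with binomial errors, and binary
    risk), aggregated from local species occurrences to one-degree
    grid-cell assemblages. A synthetic-data generator reproduces the
    statistical structure of the real inputs so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
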