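Package: lfcrtemp
Title: Temperature Response Analysis for Hybrid Linear Flow Channel
    Sulphate-Reducing Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temperature response of hybrid linear
    flow channel reactors (LFCRs) that couple biological sulphate reduction
    to partial sulphide oxidation in a floating sulphur biofilm. Provides a
    mechanistic well-mixed reactor simulator with a stepwise cooling
    schedule, pseudo-steady-state reduction of sampled time series to
    volumetric sulphate reduction and sulphide oxidation rates,
    stoichiometric partitioning of lactate flux between fermentation and
    incomplete oxidation, one- and two-regime Arrhenius fits with critical
    temperature estimation, sulphur mass-balance ledgers across biofilm,
    effluent and unaccounted pools, and alpha/beta diversity summaries of
    amplicon sequence variant count tables, together with a reproducible
    scenario pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
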