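Package: nppdb
Title: Harmonization of Net Primary Production Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing multi-site net primary production (NPP)
    databases: a validated multi-table data model (CSV and SQLite), hierarchical
    summation of biomass components into gated aggregate levels, method-specific
    measurement-uncertainty estimation and propagation built on a catalogue of
    reduction factors for field methods, rule-based biome and management
    classification, Koppen-Geiger main climate classes and aridity indices from
    monthly normals, stratified quality control, and uncertainty-weighted
    nonlinear climate-NPP (Miami model) regression. Includes a synthetic
    database generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    DBI,
    RSQLite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
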