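Package: comorbidlink
Title: Sex-Stratified Comorbidity Modeling and Literature-Based Gene
    Overlap Analysis for Disease Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for quantifying the comorbidity between
    two diseases and exploring its molecular basis. Scales sex-stratified
    conditional co-occurrence probabilities observed in a clinical cohort to
    population-level 2x2 contingency tables using population prevalence and
    incidence rates, and tests the association with odds ratios, relative
    risks, and a log-space Fisher exact test that remains stable for
    populations of ten million. Scores literature-derived gene-disease
    associations with an upper-tail binomial statistic and
    Benjamini-Hochberg false-discovery-rate control, tests cross-disease
    gene-set overlap against a finite gene universe, computes directed
    gene-network topology and centrality profiles with hub-gene ranking, and
    assembles signed disease-gene-disease candidate pathways. Includes
    seeded synthetic-data generators for cohorts, literature observation
    panels, networks, and gene sets so every stage is testable without
    external data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
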