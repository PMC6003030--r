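Package: tplcea
Title: Cost-Effectiveness Analysis of Diagnostic Strategies for Threatened Preterm Labor
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing seven diagnostic
    strategies (cervical length thresholds, qualitative and quantitative fetal
    fibronectin, cervical interleukin-6, biomarker combinations) for women presenting
    with threatened preterm labor in singleton pregnancy at 24-34 weeks of gestation.
    A decision tree routes women by test result and delivery-within-7-days status into
    treated or untreated pathways; non-deliverers enter a weekly Markov cohort model of
    home follow-up, re-hospitalization and delivery up to 37 weeks. The package computes
    expected costs (2012 euros) and expected serious neonatal adverse events per
    strategy and gestational-age stratum, ranks strategies with simple and extended
    dominance and incremental cost-effectiveness ratios, runs deterministic scenario
    analyses and a probabilistic sensitivity analysis summarised by
    cost-effectiveness-plane quadrant, and ships an individual-level microsimulation
    that serves as a brute-force oracle for the cohort model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
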