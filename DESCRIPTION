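Package: microrecov
Title: Predicting Gut Microbiome Recovery After Antibiotic Disturbance
Version: 0.1.0
Authors@R:
    person("Microrecov", "Developers", email = "microrecov@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing longitudinal gut-microbiome profiles around
    an antibiotic disturbance. Labels subjects as recoverers or non-recoverers
    from Gini-Simpson diversity using an interquartile-range rule, identifies
    predictive recovery-associated bacterial species (p-RABs) with an ensemble
    of six feature selectors (cross-cohort Wilcoxon consensus, two
    gradient-boosted tree classifiers, discriminant principal-component
    correlation networks, and two differential co-occurrence network driver
    scores) combined by cross-validated AUC, computes taxonomic diversity,
    Rao functional diversity and functional redundancy from a gene-content
    network, ships a logistic recovery predictor, and characterises
    co-occurrence network topology and vulnerability. Includes a synthetic
    multi-cohort data generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
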