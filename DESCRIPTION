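Package: diffcornet
Title: Differential Spearman Correlation Networks for Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds significance-thresholded Spearman correlation networks
    for two clinical groups over a shared physiological and cognitive
    variable panel, computes node- and edge-level topology metrics
    (degree, neighbourhood connectivity, stress, betweenness, closeness,
    edge betweenness), and compares the two networks' topology with
    tie-corrected Mann-Whitney U tests and effect sizes r = Z/sqrt(N) to
    detect physiological dyshomeostasis. Includes a Gaussian-copula
    synthetic-cohort generator with target Spearman structure, group
    assignment and descriptive comparison utilities, and Cytoscape-ready
    GraphML/SIF exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    MASS,
    car,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
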