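Package: strokeconn
Title: Connectome-Based Phenotyping of Stroke Recovery After rTMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative tangent-space modelling of resting-state functional
    connectivity and machine-learning phenotyping of stroke recovery
    trajectories. Builds a normative model of region-by-region functional
    connectivity from a healthy reference cohort on the manifold of symmetric
    positive-definite matrices, flags per-patient 3-sigma connectivity
    anomalies (hypo-/hyperconnected pairs) after excluding the highest-variance
    third of pairs, clusters four-timepoint trajectories on standardized stroke
    scales (NIHSS, FMA, BI, WMFT) by agglomerative hierarchical clustering with
    silhouette-optimal K, and compares connectivity features across recovery
    phenotypes with a nonparametric statistical battery (Friedman with
    Kendall's W, Dunn post hoc, Kruskal-Wallis, gated t/Wilcoxon,
    chi-square/Fisher). Includes a seeded synthetic-cohort generator so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    pracma,
    withr
Config/testthat/edition: 3
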