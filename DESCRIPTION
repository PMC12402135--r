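Package: convorg
Title: Cortico-Subcortical Converging Organization from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing how cortical regions converge onto
    subcortical regions in resting-state functional connectomes.
    Implements partial-correlation functional connectivity by node-wise
    multiple regression with random-effects group inference, Louvain
    consensus community detection with a resolution sweep and
    silhouette-based model selection, degree-preserving null-model
    validation of graph metrics, hub typology from participation and
    within-module degree, convergence and distance statistics over
    bipartite cortico-subcortical graphs, and targeted-attack local
    efficiency analysis. A synthetic multi-subject time-series generator
    with planted communities and planted convergence makes every stage
    testable without imaging data, and a packaged table of converging
    cortical regions supports the convergence analyses directly.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
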