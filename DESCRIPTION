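Package: topoqspr
Title: Degree-Based Topological Indices, QSPR Regression and MCDM Drug Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes eleven degree-based topological indices (Zagreb, harmonic,
    hyper-Zagreb, forgotten, atom-bond connectivity, Randic, sum-connectivity,
    geometric-arithmetic, Sombor and Nirmala) of hydrogen-suppressed molecular
    graphs from their endpoint-degree edge partitions, recovers edge partitions
    from printed index vectors by exact integer search, screens index-property
    correlations and fits enter-method multiple linear regression (QSPR) models
    for physicochemical properties of 22 dry-eye-disease drugs, and ranks the
    drugs with the TOPSIS and VIKOR multi-criteria decision methods. Ships the
    study tables as validated plain-text fixtures plus seedable synthetic-data
    generators so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
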