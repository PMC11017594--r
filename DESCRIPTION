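Package: mvconsensus
Title: Consensus Multi-View Feature Selection for Paired Multi-Omic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Feature selection for small-sample, high-dimensional multi-omic
    case/control studies with paired baseline and post-treatment sampling.
    Implements model-free mean-variance (MV) screening of individual
    features, l1-penalised sparse linear discriminant analysis with
    leave-one-out cross-validated penalty selection, joint sparse
    association and classification across two or three omic views via
    block coordinate descent, and a consensus rule that intersects the
    selections of all methods and augments them with highly correlated
    partners and top joint-model loadings. Ships the matching
    view-specific preprocessing (median normalisation, taxon aggregation,
    prevalence filtering, relative abundance, paired differencing,
    log-CPM) and a seeded synthetic multi-view generator with planted
    ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
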