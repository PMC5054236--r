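Package: newsworthy
Title: Modeling the Newsworthiness of Health Science Articles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying which published health science articles
    receive journal press releases and mainstream news coverage. Builds
    labeled citation corpora by matched case-control sampling (same
    journal/issue/year), featurizes titles, abstracts and MeSH headings
    as prefixed uni- and bigram counts, fits an L2-regularized logistic
    model evaluated by nested cross-validated AUC, ranks robustly
    predictive features via bootstrap confidence-interval bounds, and
    fits a supervised topic model (sLDA with a softmax response over
    empirical topic frequencies) by variational EM. Includes seeded
    synthetic-corpus generators so every stage is testable without the
    original datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
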