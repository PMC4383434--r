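Package: dentalcbr
Title: Case-Based Reasoning for Posterior-Tooth Restoration Choice and
    Longevity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinical decision support for choosing a posterior-tooth
    restoration material (amalgam versus composite) and predicting how
    long the restoration will last.  Implements a full case-based
    reasoning (CBR) cycle over a 43-attribute dental case schema:
    retrieval by expectation-maximization clustering of mixed
    categorical/continuous attributes with a Bayesian-network cluster
    classifier, reuse by a mixture of experts (a Bayesian network and a
    multilayer perceptron combined by a second perceptron), revision by
    per-cluster confidence limits, and retention with cache
    invalidation.  Ships a synthetic case-base generator with known
    latent structure, exact small-sample Mann-Whitney comparison of
    competing predictors, 5x2 cross-validation and leave-one-out error
    estimation, and yearly usage/duration/failure-rate reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
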