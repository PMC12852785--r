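Package: secureMICE
Title: Secure Distributed Multiple Imputation by Chained Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiple imputation by chained equations (MICE) executed under
    honest-but-curious secure multiparty computation. Provides a fixed-point
    additive-secret-sharing engine over a 192-bit ring with trusted-dealer
    Beaver triples, secure linear and logistic regression (closed-form and
    gradient-descent paths, Chebyshev polynomial sigmoid), the chained
    imputation loop with Rubin's-rules pooling, a partitioned-dataflow
    variant for horizontally distributed data behind a pluggable secure
    vector backend, simulation-scenario generators for missing-at-random and
    missing-not-at-random designs, and the evaluation statistics (coefficient
    bias/SD/rMSE, imputation and prediction error, AUC, discrepancy counts)
    used to compare secure and plaintext analyses. A plaintext reference
    pipeline with an identical contract serves as the correctness oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
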