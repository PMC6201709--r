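Package: prognae
Title: Prognostic Subtyping of High-Risk Neuroblastoma by Autoencoder-Based
    Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates gene-expression and copy-number profiles of high-risk
    neuroblastoma cohorts with a fully connected autoencoder, screens features
    by univariate Cox proportional-hazards regression, clusters the
    survival-associated bottleneck features with K-means to define two
    prognostic subtypes (ultra-high-risk G1 versus G2), transfers the labels
    to single-omics cohorts with supervised classifiers, and runs downstream
    differential expression and gene-set overrepresentation analysis. Ships a
    synthetic multi-cohort generator with planted subtypes and exponential
    survival so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    cluster,
    e1071,
    xgboost,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, mclust
Config/testthat/edition: 3
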