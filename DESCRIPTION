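Package: neodx
Title: Dried-Blood-Spot Metabolite Screening and Diagnostic Models for
    Neonatal Hypoxic-Ischemic Encephalopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for targeted newborn-screening metabolomics
    panels (amino acids, acylcarnitines, nucleosides, succinylacetone,
    lysophosphatidylcholines measured in dried blood spots). Implements
    nonparametric univariate screening with false-discovery-rate control,
    Spearman time-association, principal component analysis of significant
    compounds, differential correlation-network clustering (adjacency-change
    matrices, Ward linkage, silhouette-selected cluster count),
    over-representation analysis with ambiguous-identification marker-set
    expansion and a consensus significance rule, orthogonal partial least
    squares discriminant analysis (OPLS-DA) with VIP scores and leave-one-out
    cross-validation, and a stepwise-built logistic diagnostic model with
    feature expansion, VIP prefiltering, AIC forward selection, backward
    p-elimination and repeated train/test split validation. Ships a seeded
    synthetic cohort generator emulating the rat model group designs so the
    whole pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics,
    optparse
Config/testthat/edition: 3
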