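Package: megax
Title: Mega-Analysis of Multi-Study Case/Control Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for "mega-analysis" of case/control gene-expression
    studies: per-study log2 fold-change effect sizes with Welch standard
    errors, inverse-variance fixed- and random-effects pooling with
    Cochran's Q, I-squared and DerSimonian-Laird tau-squared, a
    heterogeneity-driven model-selection rule, a partial mega-analysis
    over the top fraction of studies ranked by absolute effect size,
    multiple linear regression of study-level effects on study
    covariates, assembly of signed literature-derived diagnostic and
    prognostic gene networks with expression-consistency filtering, and
    hypergeometric over-representation analysis of the resulting gene
    lists with Benjamini-Hochberg false-discovery control. Includes a
    synthetic multi-study data generator with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
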