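Package: irlncPairs
Title: Immune-Related lncRNA Pair Signatures for Survival Prognosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs and evaluates rank-based prognostic signatures built
    from within-sample binary comparisons of immune-related long noncoding
    RNA (lncRNA) expression. Provides the full workflow: screening of
    immune-related lncRNAs by coexpression with immune genes, tumor/normal
    differential-expression filtering, construction of the 0-or-1 pair
    matrix with a validity-frequency filter, univariate Cox screening,
    repeated cross-validated L1-penalized Cox selection, risk scoring,
    time-dependent ROC analysis with a Youden-optimal cutoff, Kaplan-Meier
    stratification, clinical and immune-landscape association statistics,
    and a seeded synthetic-cohort simulator with known planted truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
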