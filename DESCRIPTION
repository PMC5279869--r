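Package: ctxcausal
Title: Context-Specific Causal Signaling Network Inference from
    Interventional RPPA Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for learning context-specific causal
    signaling networks from reverse-phase protein array (RPPA) time-course
    data collected under kinase inhibition. Includes loading normalization
    by median centering, two-batch normalization against shared vehicle
    controls, sample quality control, identification of salient abundance
    changes under inhibition (paired t tests with a peak-window retest and
    a two-stage adaptive FDR procedure), construction of causal descendancy
    matrices, joint learning of interventional dynamic Bayesian networks
    across (cell line, stimulus) contexts with a curated prior network,
    and held-out-inhibitor assessment via descendant-set ROC analysis.
    A synthetic-data generator produces ground-truth context networks and
    RPPA-like interventional time courses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
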