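Package: m6Apattern
Title: m6A Regulator Patterns, Immune Context and a PCA-Based Prognostic
    Score for Lung Adenocarcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise N6-methyladenosine (m6A) modification
    patterns in bulk expression cohorts: resampling-based consensus
    clustering of samples on the 23-gene m6A regulator panel with
    delta-area selection of the cluster number, single-sample gene-set
    enrichment (ssGSEA) and GSVA-style pathway scoring, empirical-Bayes
    moderated differential expression, a PCA-derived per-sample score
    (PC1 + PC2 of the prognostic phenotype-gene signature), survival
    analysis from first principles (Kaplan-Meier, log-rank, Cox
    proportional hazards, maximally selected log-rank cutpoint), and
    mutation-burden / immunotherapy-response comparisons.  A synthetic
    cohort generator with planted subtype, survival, immune and mutation
    structure makes the whole workflow testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
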