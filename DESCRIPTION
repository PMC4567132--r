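Package: xciscope
Title: X-Chromosome Inactivation Status Inference from Tumor Methylation
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies female tumors by X-chromosome-inactivation (XCI)
    status from CpG-island methylation beta values, XIST expression, and
    segmented copy number. Samples are stratified by histology, clustered
    on X-linked CpG-island methylation (complete-linkage hierarchical
    clustering), and assigned to one of three groups: preserved inactive X
    (Xi), partial reactivation of Xi (Xa+), or two active X chromosomes
    (two Xa), with an override that rescues Xi-arm-deletion cases showing
    selective arm-level hypomethylation. Downstream stages compare
    cancer-testis-antigen panel expression and global CpG-island
    methylation across groups (Welch t / one-way ANOVA), cross-tabulate
    clinical covariates with exact r-by-c tests, and relate XCI status to
    overall and disease-free survival via Kaplan-Meier, log-rank, and
    stage-adjusted Cox models. A synthetic-cohort generator with known
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
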