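Package: teratoclass
Title: Transcriptomics-Based Classification of Developmental Toxicants
Version: 1.0.0
Authors@R:
    person("Toxicogenomics", "Maintainers", email = "maintainers@teratoclass.org",
           role = c("aut", "cre"))
Description: Classification of developmental toxicants (teratogens) from
    hiPSC differentiation assays profiled by transcriptomics. Implements
    control-matched normalization, empirical-Bayes moderated one-sample
    t-tests with Benjamini-Hochberg FDR control, classification by counts
    of significant probe sets (SPS procedure) and by leave-one-compound-out
    L1-penalized logistic regression (top-1000 procedure), combination of
    two test systems, gene-set overrepresentation including the 'elim'
    algorithm, and an RT-qPCR confirmation classifier on a seven-gene
    panel. Ships reference score tables from a published two-assay screen
    and a synthetic-study generator so the whole pipeline is testable
    without raw microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
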