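Package: cchepnet
Title: Hepatic Transcriptome Analysis Pipeline for Recombinant-Inbred Diet Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing liver gene expression in
    recombinant-inbred mouse panels (Collaborative Cross style designs) under a
    two-diet challenge: array-level quality control by three outlier criteria,
    transcript-cluster filtering with best-probe-per-gene selection, biweight
    midcorrelation of expression with phenotypes, empirical-Bayes moderated
    differential expression by diet and strain with gene-set over-representation,
    broad-sense heritability (intraclass correlation and coefficient of genetic
    determination) with REML variance partitioning, weighted co-expression
    network module detection with module-trait statistics, and cross-analysis /
    GWAS-catalog intersection reports. A seeded synthetic-data generator with
    known ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    lme4
Config/testthat/edition: 3
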