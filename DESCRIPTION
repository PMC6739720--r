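Package: lncsalt
Title: Identification, Classification and Comparative Salt-Stress Analysis of
    Plant Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("lncsalt", "maintainers", email = "lncsalt@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for genome-wide discovery of long
    noncoding RNAs (lncRNAs) from assembled transcript models, their
    positional classification against protein-coding gene annotation
    (lincRNA, intronic, antisense, sense-overlapping), salt-stress
    differential-expression calling across a tissue-by-dose replicated
    design, tissue-specificity scoring (tau), cis/trans target-gene
    prediction with an RNA-RNA duplex energy screen, cross-species homolog
    detection by reciprocal best alignment hits with expression-concordance
    analysis, and hypergeometric GO-term enrichment. Includes a synthetic
    paired-species data generator with planted truth so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
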