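Package: hmedipr
Title: Windowed 5hmC Enrichment Analysis for Pooled hMeDIP-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of 5-hydroxymethylcytosine (5hmC)
    immunoprecipitation sequencing (hMeDIP-seq) data for two pooled
    libraries without replicates. Partitions the genome into fixed-width
    windows, counts overlapping reads and transforms them to RPKM,
    computes immunoprecipitation quality-control statistics (coverage
    saturation, CpG enrichment), stratifies coverage by genomic context
    (chromosomes, gene parts, CpG-density classes, CpG islands,
    promoters, repeats), calls differentially hydroxymethylated regions
    (DhMRs) with a conditional negative-binomial exact test, annotates
    DhMRs against gene models, and tests gene-set overlaps with
    hypergeometric statistics under Benjamini-Hochberg FDR control. A
    deterministic read simulator with planted hyper-/hypo-methylated
    windows provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
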