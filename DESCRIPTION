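Package: xciskew
Title: X-Chromosome Inactivation Skewing and Escape Analysis from Phased
    Single-Cell RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies X-chromosome inactivation (XCI) skewing and calls
    candidate XCI-escape positions from phased, cell-barcoded, UMI-tagged
    single-cell RNA-seq reads at heterozygous chrX variants. Provides
    readers for a per-read phased-variant text format (and direct
    ingestion from SAM/BAM with CB/UB tags), UMI-level allele aggregation
    with a configurable filter funnel, the MAX(X1,X2)/(X1+X2) skewing
    statistic with its four-category classification, single-cell
    biallelic escape calling with gene annotation, per-SNP two-sample
    comparison (two-proportion Z, Pearson chi-square, Bonferroni /
    Hochberg / Hommel / FDR corrections, Haldane-corrected Woolf odds
    ratios), and a synthetic read generator with ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicAlignments,
    IRanges,
    jsonlite,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
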