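Package: absQTLseq
Title: Modified QTL-seq (Bulked Segregant Analysis) with |Delta(SNP-index)| for Heterozygous Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked segregant analysis (QTL-seq) from pooled whole-genome
    resequencing of two phenotype bulks. Computes per-pool SNP-indices from
    allele depths, sliding-window averages of SNP-index, Delta(SNP-index) and
    |Delta(SNP-index)|, empirical quantile thresholds, and merged candidate
    intervals with sparse-interval filtering. A pooled-sequencing simulator of
    F1 crosses between heterozygous parents, including a mosaic-reference
    ("pseudoexchange") model, supports power comparisons showing why the
    sign-free |Delta(SNP-index)| statistic outperforms signed Delta(SNP-index)
    when the reference genome is not a parental haplotype.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
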