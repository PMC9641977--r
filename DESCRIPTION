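Package: srnaflow
Title: Small RNA Classification, Fractional Counting and
    Genotype-Temperature Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying endogenous small RNA expression
    across strain genotypes and rearing temperatures in nematodes.
    Builds strain-specific pseudo-reference genomes by substituting SNPs
    and short indels into a reference and lifting feature annotations
    with class-specific retention filters; trims, demultiplexes and
    length-filters small RNA reads; places reads by perfect full-length
    matching on both strands with a multi-mapping cap; classifies reads
    into the 22G/26G endo-siRNA, 21U-piRNA and microRNA taxonomy and
    produces fractional (1/N) counts per feature, chromosome, piRNA
    cluster and genomic window; fits per-feature
    genotype + temperature + interaction models with voom precision
    weights and empirical-Bayes moderation and assigns a five-group
    differential-expression classification; and computes
    Argonaute/RdRP target-set overlap, correlation and rank-sum
    statistics. A synthetic-data generator produces two-strain toy
    genomes, variants and reads with known effect structure plus truth
    tables for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    edgeR,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
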