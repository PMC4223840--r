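Package: pooldiff
Title: Differential Expression and Differential Polymorphism from Pooled RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of transcription level and sequence polymorphism
    from pooled RNA-seq of selected insect strains against a susceptible
    parent. Implements the Audic-Claverie two-library count test with
    Benjamini-Hochberg correction and RPKM quantification, pooled
    allele-frequency differential-SNP calling with homopolymer, quality and
    coverage filters, codon-aware annotation of SNP consequences against GFF3
    gene models, Fisher-based functional-category enrichment, and a
    synthetic-data generator emulating the pooled three-strain, two-library
    design so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
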