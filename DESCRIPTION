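Package: mutscreen
Title: Post-Alignment Mutation Screening, Consensus Calling and Clinical Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the post-alignment core of a clinical mutation-screening
    workflow: per-base pileup statistics from SAM alignments with read- and
    base-quality filtering and PCR-duplicate marking, left-aligned parsimonious
    variant normalization so calls from different mappers and variant callers
    can be merged into consensus records, gene-model-based effect prediction
    (codon, amino-acid and frameshift consequences), per-variant two-tailed
    Fisher's exact tests with Benjamini-Hochberg FDR correction,
    coverage/allele-frequency filtering, dbSNP/GWAS/hotspot membership
    flagging, a cross-reference link matrix to public databases, and a
    one-line-per-variant summary table with per-patient VCF output. A fully
    deterministic synthetic-fixture generator produces genomes, gene models,
    reads and caller-jittered VCFs so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    parallel,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
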