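Package: haploscan
Title: Strain Haplotype Contrast Scanning and Cohort Statistics for
    Mouse Modifier Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genomic intervals whose haplotype strain-distribution
    pattern separates a designated group of inbred mouse strains sharing one
    founder haplotype from strains carrying distinct haplotypes, as used to
    nominate modifier loci of strain-specific tumor phenotypes. Provides
    genome segmentation over per-strain haplotype block tracks, a
    configurable strain-contrast predicate, gene-overlap annotation with
    functional category summaries, Kaplan-Meier and log-rank cohort
    statistics, deletion-allele genotyping and truncation-product arithmetic,
    and a seeded synthetic mosaic-genome and cohort simulator so the whole
    pipeline is testable without external downloads.
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
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
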