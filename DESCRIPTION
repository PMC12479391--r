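Package: minigeneiso
Title: Isoform Assembly and Annotation for Minigene Splicing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds artificial reference genomes (FASTA/GTF) for minigene
    splicing reporter constructs, clusters spliced sequencing reads into
    isoform models by intron chain, annotates each isoform against the
    cloned exon structure with an exon-skipping/intron-retention event
    nomenclature, and reports per-sample isoform proportions and cohort
    occurrence. Includes a synthetic-data generator producing constructs,
    isoforms and aligned read sets with known ground truth, so the whole
    pipeline can be exercised without external aligners or assemblers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python with openpyxl (optional, for xlsx report export)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
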