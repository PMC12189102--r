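Package: svscape
Title: Population Genomics of Insertions, Deletions and Structural
    Variants in Multi-Breed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream population-genomic analysis of insertion/deletion
    variation in multi-breed resequencing cohorts: hard filtering and
    three-way size classification of indels and structural variants,
    breakpoint-density hotspot detection in 100 kb genome bins,
    permutation Z-score tests for overlap enrichment against QTL and
    regulatory-element tracks, transposable-element content
    classification against RepeatMasker annotations, ANNOVAR-style
    genomic region assignment, Weir-Cockerham and Hudson Fst selection
    scans with 50 kb / 20 kb sliding windows, and LD-based tagging of
    variants by eQTL/sQTL SNPs. Ships a Balding-Nichols synthetic cohort
    generator with planted ground truth so the full pipeline runs and
    validates at desk scale without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
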