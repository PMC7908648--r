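Package: svintegrate
Title: Integration, Genotyping and Prioritization of Structural Variants
    from Short-Read Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates depth-of-coverage CNV calls with split-read and
    discordant-pair structural variant calls from short-read whole-genome
    sequencing. Genotypes copy-number variants from normalized read depth,
    assigns High/Pass/Low confidence tranches, computes population allele
    frequencies against a control-cohort evidence database, annotates
    variants with genes, disease terms and segmental duplications, and
    prioritizes rare gene-affecting variants. Includes call-set concordance
    evaluation, tabular/VCF/IGV-session/QC reporting, and a synthetic-data
    generator that emulates evidence-level input at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
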