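Package: re1screen
Title: Screening Single-Nucleotide Variants That Alter REST Recruitment at
    RE1 Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A genome-wide screen for single-nucleotide variants that modify
    binding of the transcriptional repressor REST (NRSF) to its DNA
    recognition element, the RE1.  Provides position-weight-matrix models of
    the RE1 with variable spacer lengths (0-12 bp), motif scanning of
    ChIP-seq binding regions standardized to 100 bp around the summit,
    intersection of motif half sites with SNP catalogues, allele-specific
    motif-score deltas, replicate competition-EMSA statistics (Fraction
    Bound, allele comparison, effect classes), allele-specific ChIP-seq read
    counting with an exact binomial bias test, reporter-assay and qPCR
    enrichment helpers, and a seeded synthetic-data generator with ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
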