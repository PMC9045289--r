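Package: capptss
Title: Expression-Normalized Transcription Start Site Calling for
    Bacterial 5'-End Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls transcription start sites (TSSs) from strand-specific
    5'-end sequencing read-start tracks (Capp-Switch / Cappable-seq style
    libraries) in bacterial genomes.  The pipeline intersects replicate
    tracks, associates each candidate position with its closest gene,
    classifies it as intergenic/intragenic and sense/antisense, and
    normalizes TSS strength by the RNA-seq expression (TPM) of the
    associated gene before sliding-window clustering and read-per-million
    thresholding, which removes the detection bias toward highly expressed
    genes.  Downstream layers compute 5' UTR lengths and leaderless calls,
    extract promoter windows, scan promoters for degenerate (IUPAC) sigma
    factor motifs allowing indels, and compare promoters across strains by
    global alignment with an orthology-driven score threshold.  A seeded
    synthetic-data generator with planted TSSs makes every stage testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
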