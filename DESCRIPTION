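Package: nonbscan
Title: Non-B DNA Motif Discovery and Breakpoint Co-Localization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Search engine for DNA sequences with the potential to adopt non-B
    (non-canonical) conformations, together with downstream statistics. Finds
    H-DNA (intramolecular triplex) candidates as mirror-repeat symmetries inside
    homopurine/homopyrimidine tracts (minimum arm 6 bp, 1-12 bp spacer, one
    symmetry mismatch allowed for arms of 10 bp or more) and Z-DNA candidates as
    alternating purine-pyrimidine tracts scored by dinucleotide step (GC = 25,
    GT/CA = 3, reporting threshold 75). Quantifies co-localization of motif hits
    with translocation/deletion breakpoints inside a +/- window and tests
    enrichment against a uniform permutation null, computes fluctuation-assay
    mutation frequencies and fold inductions from colony counts, and generates
    synthetic sequences with guard-protected planted motifs for validation.
    Includes GFF3/BED/FASTA/TSV interfaces and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
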