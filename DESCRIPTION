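Package: treemarker
Title: Genome-Wide Development of SSR and Intron Polymorphism Markers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-wide development of molecular markers in plant
    genomes: mining of perfect simple sequence repeats (SSRs) under per-class
    minimum repeat thresholds with canonical motif normalization, extraction of
    intron length polymorphism (ILP) markers from annotated genomes and of
    potential intron polymorphism (PIP) markers by projecting EST alignments
    onto model-species gene structures, deterministic primer design from 60-bp
    precursor flanks, an electronic PCR engine with marker validation,
    deduplication, polymorphism and universal-marker screens, marker density
    and concomitance statistics, UPGMA clustering of dominant-marker band
    matrices with bootstrap support, and detection of duplicated genome
    segments by collinear anchor chaining. Includes a deterministic synthetic
    fixture generator that plants SSR loci, gene models and duplicated
    segments with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
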