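Package: estrocon
Title: Cross-Species Conservation Analysis of Estrogen-Responsive Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for identifying estrogen-responsive genes
    from two-channel microarray experiments with an anti-estrogen rescue arm
    (control, E2, E2+ICI), mapping them to human homologs, intersecting them
    with estrogen-responsive gene lists from human cancer cell lines, and
    testing the conserved set for estrogen-response-element (ERE) motif and
    estrogen-receptor binding-site enrichment.  Includes a Significance
    Analysis of Microarrays (SAM) implementation with permutation-based
    false discovery rates, degenerate-consensus motif scanning, windowed
    binding-site assignment with randomization nulls, set-overlap statistics,
    a generic Fisher gene-set enrichment, and a seeded synthetic-data
    generator emulating every input so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
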