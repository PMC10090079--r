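Package: cas12ftools
Title: Mining and Characterization Toolkit for Compact CRISPR-Cas12f Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of hypercompact type V-F
    CRISPR-Cas12f systems from bacterial genome sequence. Detects Cas12f
    candidate genes by translated homology with a size gate and RuvC
    catalytic-residue check, finds CRISPR repeat-spacer arrays, predicts
    tracrRNAs by anti-repeat base pairing against the direct-repeat 3' end
    with a secondary-structure screen, assembles single-guide RNA scaffolds
    and stem-stabilization variant libraries, infers PAM preference from
    randomized-library cleavage sequencing (enrichment ranking, position
    frequency matrix, information content, IUPAC consensus), maps run-off
    cut sites, and quantifies editing outcomes from amplicon sequencing
    (indel-in-window classification, allele tables, deletion profiles).
    Includes seeded simulators for every input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
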