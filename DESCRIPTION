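Package: sdmprimer
Title: Site-Directed Mutagenesis Primers with Silent Restriction-Site
    Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs partially overlapping primer pairs for site-directed
    mutagenesis (SDM) that additionally introduce, or silently remove, a
    restriction-endonuclease recognition site so that mutated clones can be
    identified by a simple diagnostic digest instead of sequencing.
    Enumerates every codon-level realization of the requested amino-acid
    substitutions, searches candidate windows for restriction sites with
    IUPAC-degenerate patterns, engineers silent edits with the minimum
    number of nucleotide changes, and evaluates each candidate primer with
    a weighted seven-parameter score built on nearest-neighbor melting
    temperature and terminal duplex-stability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    optparse,
    jsonlite
Config/testthat/edition: 3
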