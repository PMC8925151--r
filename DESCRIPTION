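Package: minisatr
Title: Minisatellite Repeat-Array Analysis of PRDM9 Zinc-Finger Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing coding minisatellites such as the PRDM9
    zinc-finger array: partitioning alleles into fixed-length repeat units,
    translating units into C2H2 zinc fingers and typing them by their
    DNA-contact residues, computing slippage-aware weighted edit distances
    between repeat arrays and distance-based (neighbour-joining/BIONJ)
    phylogenies, estimating repeat-pool diversity (segregating sites,
    Watterson theta, average pairwise nucleotide diversity) and
    between-population differentiation (Nei Gst, Jost's D), classifying
    core-motif symmetry between allele pairs, and simulating minisatellite
    evolution forward in time with point mutation, slippage duplication and
    unit deletion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phytools,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
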