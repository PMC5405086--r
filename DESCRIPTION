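Package: blocksub
Title: Substitution-Pair Analysis of Gap-Free Protein Alignment Blocks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Column-wise substitution-pair statistics for BLOCKs, i.e.
    gap-free equal-length multiple alignments of orthologous protein
    sequences. Counts the 20 homo- and 190 hetero-residue pairs over all
    sequence pairs and columns, classifies substitutions as conservative
    (within the hydrophobic or hydrophilic class) or non-conservative
    (cross-class), and derives block-level evolutionary parameters: the
    hetero-pair type usage E, the non-conservative to conservative ratio
    R, the dominant pair D, residue diversity RD with the maximally
    diverse residue, and class-specific diversity CD. Per-column analysis
    reports Shannon-entropy conservation, invariant lines, and an
    eight-way physicochemical class typing. Includes a seeded synthetic
    BLOCK generator, itemized TSV reports, a cross-block correlation of R
    with literature divergence rates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
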