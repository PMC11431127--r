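Package: exgcrna
Title: Extended Genetic Code Decomposition and Analysis of RNA Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how RNA molecules decompose under ancestral
    codon repertoires. Builds the primaeval RNY code and the two extended
    codes derived from it (frame-shift and transversion routes), decomposes
    RNA sequences into maximal runs of repertoire-member triplets with
    preserved coordinates, scores recovery of functional motifs (anti-
    Shine-Dalgarno, RNase P signature, SRP helix 8, tRNA acceptor end) by
    each code, compares folding stability of biological sequences against
    thrice-shuffled controls with a weighted base-pair maximisation engine,
    summarises multiple sequence alignments as consensus sequences,
    conservation profiles and information-content logos, and compares
    one-point-per-nucleotide 3D structures by Kabsch superposition and a
    length-normalised TM-style score. A fully seeded synthetic-data module
    generates code-biased sequences, motif-planted sequences, diverged
    families with true alignments, fold-prone hairpins and toy helical
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
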