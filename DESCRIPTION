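Package: lectinpocket
Title: Comparative Analysis of C-Type Lectin Sugar-Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolution of calcium-dependent
    sugar-binding pockets in C-type lectin receptors such as Mincle.
    Screens candidate protein sequences for the EPN/QPD/EPD sugar-binding
    and WND calcium motifs and for retention of hydrophobic groove
    residues; superposes carbohydrate recognition domains by anchoring on
    the pocket calcium ion; transplants reference-bound ligands
    (glycerol, glucose, trehalose) into target pockets and classifies
    pockets as narrow or broad by van der Waals steric clash; measures
    coordination bonds, hydrogen bonds and pocket apertures; and assigns
    homologues to clades with neighbor-joining trees and maximum
    likelihood scoring under the JTT model with discrete-gamma rate
    variation and invariant sites.  Includes generators for synthetic
    pockets, idealized sugar ligands, motif-bearing sequences and
    tree-evolved alignments so the whole pipeline can be exercised
    without external structure or sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
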