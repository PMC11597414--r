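Package: duimito
Title: Comparative Analysis of Sex-Linked Mitochondrial Genomes in DUI Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of female- (F) and
    male-transmitted (M) mitochondrial genomes of bivalves with doubly
    uniparental inheritance (DUI). Reads annotated mitogenomes, computes
    base composition and AT/GC skews, start/stop codon usage, F-vs-M
    divergence (uncorrected p-distances and Nei-Gojobori dN/dS with
    Jukes-Cantor correction), scans cox2 for lineage-specific insertions
    and 3'-coding extensions with a hydropathy-based transmembrane-helix
    heuristic, characterizes unassigned (intergenic) regions as
    control-region candidates (tandem repeats, G-strings, conserved-element
    motif similarity, base-pair-maximization secondary structure),
    compares circular gene orders (duplications, transpositions,
    breakpoint distance), classifies F/M phylogenetic patterns
    (taxon-joining, gender-joining, masculinization signature) on labelled
    trees, and generates fully annotated synthetic F/M genome pairs and
    clades with planted ground truth so every stage can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
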