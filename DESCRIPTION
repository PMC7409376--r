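Package: goat
Title: Gene-Order Alignment and Synteny-Based Phylogenetics for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Gene Order Alignment Tool (GOAT), a synteny-based
    genome distance for tailed bacteriophages: per-genome gene-order profiles
    built from annotations and orthologous-group (pVOG-style) assignments, a
    symmetric family-vs-family substitution matrix averaged from reciprocal
    profile-profile hit scores, semiglobal dynamic-programming alignment of
    gene orders searched over all circular rotations and both orientations,
    and the conversion of optimal alignment scores into pairwise distances
    D = 1 - (G_AB + G_BA)/(G_AA + G_BB). Around the core metric the package
    provides BioNJ tree construction with outgroup rooting, normalized
    Robinson-Foulds topology comparison, aggregation of tabular BLAST-style
    hits into Dice and symmetrical-identity genome similarities with
    threshold-based taxon demarcation, and a seedable simulator of gene-order
    evolution (inversion, transposition, gene gain/loss, rotation) along a
    known tree for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    phytools,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
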