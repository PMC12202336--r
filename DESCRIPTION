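Package: mitocomp
Title: Comparative Analysis of Intron-Rich Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for comparative mitogenomics of fungal
    mitochondrial genomes of the kind found in entomopathogenic
    Cordycipitaceae: nucleotide composition and AT/GC skew statistics,
    region partitioning, codon usage under the mold mitochondrial genetic
    code, per-gene Kimura two-parameter distances and Nei-Gojobori (1986)
    Ka/Ks, microsatellite, tandem and dispersed repeat scanning, group-I
    intron positional-class (Pcl) homology mapping with Dollo and Fitch
    gain/loss reconstruction, and a distance-based neighbor-joining
    phylogeny stage with nonparametric bootstrap.  Ships a synthetic
    annotated-mitogenome simulator with known ground truth so that every
    analysis stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
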