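Package: syntig
Title: Sparse Syncmer Graph Assembly of Plant Organelle Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for de novo assembly of plant plastid and
    mitochondrial genomes from high-accuracy long reads. Reads are
    homopolymer compressed and reduced to closed syncmers, from which a
    sparse de Bruijn graph is built, error corrected with a banded edit
    distance search, cleaned and condensed into a unitig graph, and
    disentangled with read-phased spanning triplets. Graph components are
    classified into organelle types from profile-HMM gene hits, and each
    organelle component is resolved into a primary circular or linear
    sequence via EM copy-number estimation, canonical path enumeration,
    and an edge-visit optimisation (brute force or simulated annealing).
    Includes an exact inverted-repeat finder for quadripartite plastome
    structure, a flip-flop recombination support test, and a synthetic
    data generator for organelle genomes, HiFi-like reads and gene hit
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
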