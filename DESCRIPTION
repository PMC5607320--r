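Package: photopull
Title: Coarse-Grained Mechanical Unfolding of Membrane Proteins and
    Force-Spectroscopy Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the mechanical unfolding of membrane proteins
    in membranes of differing hydrophobicity. Implements a C-alpha
    structure-based (Go-type) force field with an implicit membrane slab
    potential, Langevin dynamics with constant-velocity pulling, native-contact
    melting scans, and a single-molecule force spectroscopy analysis pipeline:
    worm-like-chain transformation of force-distance curves to contour-length
    space, sawtooth peak detection and fitting, shift-tolerant clustering of
    force-contour-length histograms, and per-cluster peak statistics. Includes
    generators for synthetic force-distance datasets and conformational
    ensembles, plus hydrophobic-surface-area reweighting of ensembles as a
    function of membrane cholesterol content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
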