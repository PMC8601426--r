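Package: DPDfold
Title: Dissipative Particle Dynamics Reconstruction of Chromatin
    Conformations from Single-Cell Hi-C Contact Maps
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs three-dimensional polymer conformations of
    chromosomes from sparse single-cell Hi-C contact maps by dissipative
    particle dynamics (DPD): every observed contact becomes a harmonic
    restraint bond on a phantom bead-spring chain which is then equilibrated
    with a soft-repulsion force field and a pairwise momentum-conserving
    thermostat. Includes generators for gold-standard test conformations
    (equilibrium globules, closed Moore space-filling curves, polymer
    solutions), contact-map derivation, subsampling, shuffling and genomic
    binning utilities, the Modified Jaccard Index similarity metric with its
    random-matrix baseline and accuracy normalization, an exponential
    accuracy-versus-contacts model with curve fitting, and benchmark sweeps
    quantifying how reconstruction accuracy depends on contacts per bead.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
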