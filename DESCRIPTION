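Package: coacerv
Title: Coarse-Grained Modelling of Charge-Driven RNA-Protein Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying complex coacervation of RNA and globular
    proteins with a colloid-type coarse-grained model. Macromolecules are
    spherical particles interacting through a short-range 10-5 Lennard-Jones
    potential plus a size-scaled Debye-Hueckel term with effective charges
    that account for counterion condensation. The package provides a Langevin
    dynamics engine with periodic boundaries, builders for binary RNA-protein
    mixtures, a reduced five-component cytoplasm and a seeded synthetic
    polydisperse cytoplasm, contact-graph condensate detection with cluster
    size distributions, condensate volumes, radial distribution functions and
    binodal/critical-point fits, mean-squared-displacement diffusion analysis,
    an analytical two-component coacervation theory based on g(r)-convolved
    chemical potentials, and forward models for FRET efficiencies and dynamic
    light scattering correlation functions including a multi-exponential DLS
    fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
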