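Package: nucleodyn
Title: Whole-Nucleus Coarse-Grained Chromatin Dynamics and Maximum-Entropy Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-based simulation of the human nucleus at 100-KB
    resolution: a diploid genome of beads-on-a-string chromosomes coupled to
    phase-separating nucleoli and nuclear speckles inside a particulate lamina
    mesh.  Provides Langevin and Brownian integrators in reduced units, a
    semi-grand canonical Monte Carlo scheme for speckle chemistry, iterative
    maximum-entropy parameterization of the force field against Hi-C-,
    DamID- and TSA-Seq-style targets using the Adam optimizer, and an
    observable suite (contact maps, contact scaling, in-silico DamID/TSA-Seq
    profiles, mean-squared displacements with anomalous-exponent fits,
    chromosome geometry, droplet clustering, ensemble correlations).
    Deterministic toy-nucleus fixtures make the whole pipeline runnable at
    desk scale with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    igraph,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
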