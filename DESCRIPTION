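Package: condmix
Title: Coarse-Grained Simulation and Imaging Analysis of Multiphase
    Condensate Miscibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the miscibility of biomolecular condensates
    formed by charge-patterned (K/E) polyampholytes. Implements sequence
    charge decoration (SCD) and normalized patterning metrics, construction
    of linear and star (oligomerized) bead-spring polyampholytes, an
    implicit-solvent coarse-grained Langevin dynamics engine
    (hydrophobicity-scale pair potential with screened electrostatics) for
    direct-coexistence slab simulations, analysis of the resulting density
    profiles (hyperbolic-tangent fits, partition coefficients, interfacial
    tension from the pressure tensor, heterotypic-to-homotypic bond ratios),
    and a microscopy readout that segments condensates in multi-channel
    image volumes and scores their miscibility by the normalized
    centre-to-centre distance. Synthetic-data generators with embedded
    ground truth support validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    seqinr,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
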