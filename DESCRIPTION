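Package: MpipiT
Title: Temperature-Dependent Coarse-Grained Modelling of Protein LCST Phase
    Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residue-level, implicit-solvent coarse-grained modelling of
    temperature-responsive (LCST/UCST-type) phase behavior of intrinsically
    disordered proteins. Implements a temperature-dependent Wang-Frenkel pair
    potential (including a purely repulsive branch for negative well depths),
    Debye-Hueckel/Yukawa electrostatics with an analytically
    temperature-scaled dielectric constant and inverse Debye length, a
    desk-scale Langevin dynamics engine for bead-spring chains, LAMMPS export
    of production slab simulations, and the bespoke analyses used with such
    models: CLOUD-FIT cloud-point detection from slab density profiles, Flory
    scaling exponent and coil-to-globule (theta) temperature estimation from
    radius-of-gyration data, and binodal/critical-point fitting via the laws
    of coexistence densities and rectilinear diameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'MpipiT-package.R'
    'RcppExports.R'
    'analysis.R'
    'params.R'
    'sequence.R'
    'forcefield.R'
    'potentials.R'
    'engine.R'
    'lammps.R'
    'fixtures.R'
    'cli.R'
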