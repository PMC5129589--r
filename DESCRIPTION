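Package: ffmc
Title: Forcefield Transformation and Analytics for Low-Mass Protein
    Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive a low-mass, fast-sampling variant of an
    AMBER-style protein forcefield (shortened C-H bonds, removal of torsion
    potentials with a nonperipheral sp3 central atom, reduced 1-4 scaling
    factors on phi/psi, and uniform tenfold mass reduction) and to analyse
    the resulting molecular dynamics output: native-state populations,
    survival-analysis folding kinetics with Kaplan-Meier and parametric
    estimators, torsion-based fractional helicity, Karplus-equation
    J-coupling back-calculation with chi-square comparison to experiment,
    iRED Lipari-Szabo order parameters, crystallographic B-factors,
    average-linkage conformational clustering, disulfide torsion clustering
    and handedness, and classical/robust Z-score ranking of model-refinement
    quality scores. Includes seeded synthetic-data generators that emulate
    two-state folding, helix-coil transitions, cone-wobble bond vectors and
    Gaussian coordinate jitter for validation without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
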