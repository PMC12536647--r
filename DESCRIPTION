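Package: magnetopiezo
Title: Coupled Magnetoelectric and Piezoelectric Finite-Element Pipeline for
    Nanoparticle-Loaded Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear finite-element simulation pipeline for magnetoelectric
    core-shell nanoparticles (cobalt ferrite core, barium titanate shell) and a
    piezoelectric hydroxyapatite particle embedded in an alginate hydrogel.
    Implements magnetostatics with a reduced scalar potential, magnetostrictive
    eigenstrain coupling, monolithic stress-charge piezoelectricity, stationary
    electric conduction with dipole-surface boundary conditions, and von Mises
    stress post-processing on structured triangle and tetrahedral meshes. Four
    analysis stages reproduce the single-particle magnetoelectric response, the
    concentration-dependent electric-field coverage statistics of dipole
    arrays, the electromechanical response of a hydroxyapatite particle driven
    by neighbouring nanoparticles, and a three-dimensional gel/cell model of
    the stress delivered to a cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
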