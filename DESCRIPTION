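Package: vasomech
Title: Multiscale Active Mechanics of Arterial Rings with Smooth Muscle
    Calcium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the isometric wire-myograph response of small arterial
    rings by coupling a network of vascular smooth muscle cells to a
    quasi-static finite-element model of the vessel wall. Each cell carries a
    three-variable ionic model (cytosolic and store calcium, membrane
    potential) with gap-junctional coupling, which drives four-state
    actin-myosin cross-bridge kinetics and a filament-sliding contractile-unit
    model at every Gauss point of an incompressible fibre-reinforced
    hyperelastic hexahedral mesh. Pharmacological interventions
    (phenylephrine, cyclopiazonic acid, ryanodine) are expressed as linear
    parameter ramps. Includes mesh generation for one-eighth ring symmetry
    models, Gmsh MSH and legacy VTK I/O, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
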