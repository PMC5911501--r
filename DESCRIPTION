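Package: valvefsi
Title: Unified-Continuum ALE Finite-Element Simulation of Aortic Valve
    Fluid-Structure Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monolithic fluid-structure interaction of native and bileaflet
    mechanical aortic valves formulated as a single incompressible continuum,
    where a binary phase function selects a Newtonian fluid stress or a rate-form
    neo-Hookean solid stress per cell. Provides stabilized equal-order P1-P1
    finite elements on moving simplicial meshes (Arbitrary Lagrangian-Eulerian),
    Crank-Nicolson time stepping with Picard linearization and CFL-driven step
    control, linear and quality-weighted nonlinear mesh smoothing, valve closure
    by phase switching with Eikonal-based collision detection, hinge kinematics
    for bileaflet mechanical valves, parametric generators for an idealized
    aortic root, a simplified bileaflet valve in a tube, and desk-scale 2D
    valve-channel fixtures, plus post-processing of geometric orifice area,
    leaflet rotation angle, von Mises stress and the lambda2 vortex criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
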