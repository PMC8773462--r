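Package: campfem
Title: Three-Dimensional Finite Element Simulation of Intracellular cAMP
    Signaling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the synthesis, diffusion, and Michaelis-Menten
    degradation of the second messenger cyclic AMP inside three-dimensional
    cellular geometries. Linear (four-node) tetrahedral finite elements are
    assembled into sparse mass and stiffness systems and advanced in time
    with an unconditionally stable gamma-weighted implicit scheme; the
    saturating phosphodiesterase kinetics are handled by a quasi-linearization
    iterated to convergence within each time step. Includes deterministic
    tetrahedral mesh generators for a concentric-sphere cell model and a
    flattened cell-like geometry with a nuclear cavity, mesh quality
    measures, Gmsh/TetGen/VTK mesh interchange, closed-form and
    high-accuracy reference solutions (compartmental kinetics, spherical
    diffusion steady states, membrane-flux equivalence), and preset
    validation scenarios with convergence studies.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
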