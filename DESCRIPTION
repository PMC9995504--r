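Package: monami
Title: Coupled Flow and Buoyant-Blade Simulation of Seagrass Canopy Shear-Layer Instability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase, two-way-coupled model of unidirectional open-channel flow
    through a submerged bed of buoyant, inextensible, zero-flexural-rigidity
    seagrass blades. Solves the dimensionless nonhydrostatic incompressible
    momentum equations with a free surface on a terrain-following grid that
    conforms to the evolving canopy top and free surface, with a homogenized
    quadratic canopy drag assembled from per-column blade representatives in
    equilibrium with the flow. Reproduces the drag-induced canopy shear-layer
    (Kelvin-Helmholtz-type) instability and the resulting progressive waving of
    the canopy (monami), and provides diagnostics for vortex-street kinematics,
    canopy-height statistics, passive-tracer exchange across the canopy top,
    and parametric stability sweeps in Reynolds number and blade buoyancy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
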