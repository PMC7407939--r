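Package: cidep
Title: Design Calculator for Curvature-Induced Dielectrophoretic Particle Focusing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Dimensionless design models for particle and cell focusing by
    curvature-induced dielectrophoresis (C-iDEP) in circular-arc
    microchannels. Provides the closed-form point-particle pathline solution
    and its full-focusing design thresholds, the wall-repulsion-corrected
    particle dynamics (equilibrium radial coordinate and focusing-voltage
    quadrature), a parameter sweep with an empirical percent-error curve fit
    and particle-size regime classification, a two-dimensional particle
    tracer built on the analytic arc field, multi-turn channel composition,
    and a command-line design calculator. All models operate on three
    dimensionless numbers (applied-voltage strength, curvature ratio and
    particle blockage ratio) plus the real part of the Clausius-Mossotti
    factor, with converters from dimensional device, fluid, particle and
    drive parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
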