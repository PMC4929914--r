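Package: flapwing
Title: Flapping-Wing Aerodynamics of Hummingbird Fast Forward Flight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying the aerodynamics of hummingbird fast
    forward flight. Generates synthetic wing-marker kinematics with the
    stroke-plane, amplitude, twist and area-modulation structure measured
    for a calliope hummingbird flying at 8.3 m/s, reconstructs time-resolved
    triangulated wing surfaces from marker sets, computes kinematic
    descriptors (chord angle, effective angle of attack, spanwise twist,
    advance ratio), solves the incompressible Navier-Stokes equations with a
    sharp-interface immersed-boundary fractional-step method on a
    non-uniform staggered Cartesian grid, and post-processes surface
    tractions into lift, thrust and power coefficients, stroke-resolved
    averages, derived flight-performance quantities and swirling-strength
    vortex fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
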