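Package: tavsim
Title: Desk-Scale Biomechanics and Hemodynamics of Transcatheter Aortic Valves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale modelling of transcatheter aortic valve
    replacement (TAVR). Implements a modified Holzapfel-Gasser-Ogden
    fiber-reinforced hyperelastic model for valve leaflet and pericardial
    tissue, with planar-biaxial response evaluation, synthetic biaxial data
    generation, and multi-start least-squares parameter fitting; a fully
    coupled reduced-order left-heart circulation (two-Hill time-varying
    elastance chambers, lagged diode valves, Gorlin orifice aortic valve
    surrogate, three-element Windkessel afterload) with clinical cycle
    metrics (stroke volume, cardiac output, transvalvular pressure
    differences, effective orifice area); a beam-spring Lagrangian model of
    a self-expanding stent frame with radial crimping and self-expansion;
    and a minimal 2D immersed-boundary fluid-structure interaction solver
    demonstrating regularized-delta coupling and implicit contact.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    generics,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
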