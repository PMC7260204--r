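Package: beadscape
Title: Three-Dimensional Simulation of Magnetic Microbead Transport on
    Patterned Soft-Magnetic Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the motion of superparamagnetic microbeads over
    patterned soft-magnetic thin films, the transport mechanism behind many
    magnetophoretic lab-on-a-chip devices.  From a discretized magnetization
    state of the parent structure the bead's potential-energy landscape is
    computed via the magnetostatic reciprocity theorem, compressed into a
    continuously evaluable form by Fourier series in time and local
    polynomial fits in space, and the bead's equation of motion is
    integrated with wall-corrected Stokes drag, dry friction, buoyant
    gravity and automatic two/three-dimensional regime switching.  Includes
    readers and writers for OOMMF Vector Field (OVF) files, synthetic
    saturated-state generators for disc, triangle-lattice, stripe and oval
    geometries, periodic boundary handling, scenario presets and trajectory
    metrics (phase lag, looping events, rest intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
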