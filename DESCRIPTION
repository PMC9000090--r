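Package: cortexgel
Title: Mechanochemical Simulation of the Excitable Actomyosin Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coupled dynamics of RhoA signalling and actomyosin
    mechanics in the cell cortex. Provides the well-mixed ordinary
    differential equation model with viscoelastic strain-dilution feedback,
    one- and two-dimensional active-gel partial differential equation models
    with advective mechanical feedback on periodic domains, linear stability
    analysis of homogeneous states (dispersion relations, fastest-growing
    modes, wavelength/frequency/wave-speed maps), regime classification and
    phase diagrams, stimulus protocols for local-activation experiments, and
    topological analysis of oscillation phase fields (defect detection by
    winding number, phase velocity and vorticity, energy-enstrophy
    statistics, and power-law tail fits of phase-speed distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
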