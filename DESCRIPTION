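Package: vesseladapt
Title: Integrative Simulation of Resistance Artery Biomechanics and Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic single-segment model of the resistance artery wall:
    passive matrix, active smooth muscle and cytoskeletal stresses in a
    Laplace mechanical equilibrium under Poiseuille shear, coupled to four
    adaptation processes (myogenic/shear control of tone, smooth muscle cell
    length plasticity, eutrophic matrix remodeling and trophic growth of wall
    cross-sectional area) as a stiff five-state ODE system. Provides stiff
    time integration with collapse/runaway guards, steady-state solving with
    root polishing, model variants and software knockouts, pressure-radius
    curves, step-response and steady-state-map protocols, parameter
    sensitivity matrices and a dilator instability scan, plus YAML
    configuration, CSV/JSON writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
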