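Package: biobattery
Title: Mechanistic Simulation of a Phenazine-Producing E. coli Bio-Battery Anolyte
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Zero-dimensional mechanistic model of an engineered, phenazine-producing
    Escherichia coli culture serving as the anolyte of a redox-flow-battery half-cell.
    Couples Monod substrate uptake, Luedeking-Piret phenazine production, Hill-type
    product toxicity and first-order mediator degradation to a Nernstian electrode
    with lumped ohmic loss. Provides explicit-Euler batch simulation, charge-discharge
    cycling with a voltage cut-off, design-space sweeps over production strength and
    biomass loading, sensitivity analyses for host tolerance and mediator stability,
    and export of the microbial subsystem as SBML Level 2 Version 4 with a generic
    rate-rule integrator for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
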