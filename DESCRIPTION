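Package: paccsim
Title: Eco-Evolutionary Dynamics of Polyaneuploid Cancer Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the coupled ecological and evolutionary dynamics of a
    state-structured cancer cell population with a proliferative aneuploid
    (2N+) state and a drug-resistant polyaneuploid (PACC) state. Fitness of
    the structured population is the spectral bound of a 2x2 population
    projection matrix, and a continuous resistance trait evolves up the
    fitness gradient at a rate set by the population's evolvability.
    Implements the single-state (tumor heterogeneity), non-proliferation and
    evolutionary-triage hypotheses, three PACC-targeted drugs (KIFC1
    inhibitor, cyclin/CDK inhibitor, metabolic modulator), piecewise-constant
    therapy schedules, analytic reference results, outcome classification and
    a scenario battery covering continuous, intermittent and targeted-window
    regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
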