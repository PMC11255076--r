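Package: ventltf
Title: Modeling Ventilatory Long-Term Facilitation During Interval Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modeling long-term facilitation (LTF) of breathing
    during interval exercise with mild inhaled CO2. Implements a linear
    excitatory/inhibitory neuronal-pool model and its canonical second-order
    step-response form, a two-compartment (central/peripheral) chemoreflex
    model driven by end-tidal CO2 deviations, a synthetic-data generator for
    7-subject interval-exercise ventilation records, and a decomposition
    pipeline that fits chemoreflex gains, removes the chemoreceptor-mediated
    component, detects the facilitation onset, fits the second-order LTF
    response and extrapolates its steady state, together with the supporting
    variance statistics (Bartlett test, combined standard deviations, paired
    t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
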