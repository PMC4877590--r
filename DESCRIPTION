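Package: monowave
Title: Thermodynamics of Acoustic pH Pulses in Lipid Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for acoustic pulses propagating along charged
    lipid monolayers at the air-water interface. Converts lateral
    pressure-area isotherms into isothermal compressibility and sound
    velocity profiles, fits the Boltzmann sigmoid of transition pressure
    against subphase pH to extract the head-group pKa and dissociation
    degree, evaluates Gouy-Chapman head-group potentials and the Boltzmann
    shift of interfacial pH, extracts pulse velocity, amplitude and damping
    from two-sensor time series, and calibrates ratiometric fluorescence
    intensity ratios into interfacial pH traces. A synthetic-data module
    emulates the Langmuir-trough instrumentation so every stage is testable
    without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
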