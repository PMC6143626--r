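Package: conformsim
Title: Copying Simulations and Acquisition-Curve Diagnostics for
    Conformist Social Learning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying when sigmoidal acquisition curves do and do
    not indicate conformist (positive frequency-dependent) social learning.
    Provides an agent-based two-variant copying simulator with pluggable
    learning rules (random copying, variant preference, demonstrator
    subgroups, and a reference conformist rule), the competing measurement
    conventions for variant frequency (current population state, full
    behavioural history, recent-history windows) and for adoption outcomes,
    binned acquisition curves with count-weighted linear and sigmoid fits
    compared by r-squared, a closed-form model of direct (variant
    preference) bias, and scenario drivers covering regime-union artefacts
    from 50/50 starting conditions, drift-driven sigmoids from small
    demonstrator pools, and the sensitivity of behaviour-frequency measures
    to history-window size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
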