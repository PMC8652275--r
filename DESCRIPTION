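Package: blanketflow
Title: Markov Blankets, Synchronization Maps and Stochastic Control at
    Gaussian Steady State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stationary stochastic processes
    whose Gaussian steady state carries a Markov blanket.  Provides
    partitioned Gaussian algebra (blanket detection, conditionals,
    expected states), existence tests and construction of the
    synchronization map linking internal and external coordinates,
    stationary diffusions with dissipative and solenoidal flow,
    variational free-energy and precision-weighted prediction-error
    diagnostics, active-inference control objectives, and linear
    stochastic realizations via integrator chains with PID-like gain
    extraction.  Includes seeded fixture generators, figure-style
    experiment presets and a config-driven experiment runner with
    deterministic CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
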