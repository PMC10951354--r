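Package: cerebsync
Title: Cerebellar State Estimation and Behavioural Synchronisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator of cerebellar-dependent motor coordination cast as
    active inference. A variational free-energy filter over a linear
    stochastic state-space model (the cerebellar generative model) is
    coupled in closed loop to stochastic Kuramoto phase oscillators
    standing in for extra-cerebellar circuits that produce whisking,
    respiration and limb movements. Includes the recognition (filtering)
    dynamics with analytic free-energy gradients, behavioural-regime
    schedules and perturbations, preset experiments for
    whisking-respiration synchronisation and quadruped limb-tail
    coordination, circular phase-locking and stride-averaging metrics, a
    YAML-configured command-line interface and CSV/JSON serialisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
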