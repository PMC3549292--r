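Package: diathesim
Title: Agent-Based Diathesis-Stress Simulation of Depressive Episode Dynamics
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates daily depressive symptom dynamics in heterogeneous
    cohorts from a diathesis-stress interaction: each agent carries a
    lognormally distributed vulnerability (diathesis) and experiences
    independent daily lognormal stress; stress burden accumulates through
    activation and decays through diathesis-modulated adaptation, and
    symptoms are the trailing 14-day mean of the burden. A diagnostic
    threshold with a remission-stringency hysteresis segments the
    continuous symptom traces into nominal depressive episodes. Built-in
    epidemiologic analyses (Kaplan-Meier onset and recovery curves,
    recurrence by episode history, baseline-symptom stratification,
    parameter sweeps) reproduce the apparently complex epidemiologic
    patterns - declining incidence, history-dependent recurrence,
    baseline-symptom risk elevation and duration-dependent recovery -
    that emerge when a threshold is applied to a continuous process.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
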