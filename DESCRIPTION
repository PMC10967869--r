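Package: dcftwin
Title: Digital Twin for Industrial Dynamic Crossflow Filtration
Version: 0.1.0
Authors@R:
    person("dcftwin", "maintainers", email = "dcftwin@example.org", role = c("aut", "cre"))
Description: Mechanistic-empirical process dynamics model of dynamic crossflow
    filtration (DCF) with rotating membrane discs: segmented resistance-in-series
    fouling model (membrane, pore and cake resistances), PLC control emulation
    (flow- vs TMP-controlled modes, torque-driven retentate valve with
    hysteresis), model-based full-factorial design of experiments, quadratic
    response-surface metamodel with analytic optimal permeate-flow setpoint, a
    closed-loop digital twin (torque soft sensor, 5-min optimization cycles,
    TMP-mismatch model adaptation), and a virtual plant for closed-loop testing
    and campaign comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
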