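Package: coopclim
Title: Heat-Balance Simulation and Variable-Universe Fuzzy PID Ventilation
    Control for Multi-Tier Layer Houses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Dynamic heat-balance modelling of multi-tier caged layer houses
    under combined positive- and negative-pressure ventilation (CPNPV), and
    closed-loop temperature regulation of the ventilation system. Implements
    the house heat budget (solar gain, CIGR flock heat production,
    evaporative cooling-pad ventilation losses split between positive-pressure
    fans and guide plates, floor and envelope exchange), a dual-input
    quad-output Mamdani fuzzy PID controller that schedules the PID gain
    corrections and the positive/negative ventilation split coefficient, a
    variable-universe extension with proportional-exponential scaling factors,
    on-off and fixed-gain PID baselines, a synthetic minutely weather driver,
    and the control-performance metrics (MAE, RMSE, R2, overshoot, response
    time, mean oscillation index) used to compare the controllers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
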