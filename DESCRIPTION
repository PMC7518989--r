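Package: heatsd
Title: System Dynamics Simulation of Heat-Wave Mortality and Mitigation
    Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A daily stock-flow (system dynamics) model of heat-wave
    mortality in a large city. Daily maximum temperature drives an inflow
    of heat-affected people into a stock that is drained by treatment and
    by heat-attributable deaths; treatment capacity is modulated by
    economic, health-system and governance adaptation factors built from
    city indicators. Includes detection of heat-wave episodes under the
    China Meteorological Administration consecutive-day rules, a scenario
    engine for marginal-temperature and mitigation experiments (hospital
    bed readiness, minimum-living-allowance increases), least-squares
    calibration of the free parameters against daily death series, and
    generators for synthetic heat-wave climate fixtures, city profiles
    and Poisson daily death counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
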