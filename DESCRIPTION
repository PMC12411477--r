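Package: twinvax
Title: Discrete-Event Simulation of a Digital Twin for Immunisation Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, seed-reproducible discrete-event simulator of an
    immunisation-service digital twin. Couples vaccine cold-chain thermal
    monitoring (Ornstein-Uhlenbeck storage-temperature dynamics, hourly
    5-minute sensing windows, 3/7 degree-Celsius alert thresholds, excursion
    detection, equipment-malfunction injection) with population
    vaccination-schedule tracking (stratified synthetic populations, Cochran
    sample sizing with finite-population correction, due dates, age-dependent
    reminder ladders, dose ledgers, coverage reports), linked through a
    store-and-forward FIFO telemetry buffer that models intermittent network
    connectivity. Ships scenario presets for stable operation, equipment
    malfunction and network outage, plus indicator summaries (means, standard
    deviations, Student-t confidence intervals, alert response times).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
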