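Package: avoidephys
Title: Single-Unit and Behavioral Analysis of Platform-Mediated Active Avoidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tone-signaled, platform-mediated active
    avoidance experiments with extracellular single-unit recordings from
    prefrontal cortex. Provides peri-event spike binning and Z-score
    classification of excitatory and inhibitory responses against a pretone
    baseline, interspike-interval based detection of inhibition onset latency,
    behavioral endpoints (platform occupancy, avoidance latency, freezing,
    conditioned suppression of bar pressing), laser-modulation classification
    for optrode recordings, exact contingency-table statistics for population
    proportions, and a seeded inhomogeneous-Poisson generator of synthetic
    cohorts so every stage of the pipeline is verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
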