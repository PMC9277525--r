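Package: hdmonitor
Title: Remote Digital Monitoring Pipeline for Huntington Disease Active Tests
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulation, feature extraction, quality control, aggregation and
    cross-sectional validation statistics for smartphone- and smartwatch-based
    active tests used in remote monitoring of Huntington disease. Implements
    the eight-test battery (digital SDMT, Stroop word reading, speeded tapping,
    shape drawing, chorea, balance, U-turn and walking tests), converts raw
    inertial-sensor and touchscreen streams into single scalar features,
    applies configurable execution quality criteria including device-placement
    exclusions, median-aggregates features over two-week intervals with
    minimum-observation rules, and computes test-retest intraclass
    correlations, convergent-validity correlations, and known-groups
    comparisons on age- and study-adjusted residuals. A synthetic-cohort
    generator with a latent severity scale provides a recoverable ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
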