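Package: mcsbench
Title: Multi-Directional Standing Lower-Limb Strength Assessment and
    Normative Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing maximal voluntary isometric contraction
    (MVC) force traces recorded on a platform-mounted triaxial force
    sensor during standing lower-limb strength tests.  Emulates the
    strain-gauge/amplifier/ADC acquisition chain (force-voltage
    conversion, zero-offset calibration, quantization), extracts MVC
    scores by zero-phase Butterworth low-pass filtering followed by a
    sliding-window maximum-mean search, orchestrates the six-direction
    frontal/sagittal assessment protocol with body-mass normalization
    to relative strength (N/kg), and benchmarks cohorts with
    independent-samples t-tests, one-way ANOVA with Games-Howell post
    hoc comparisons, and two-way ANOVA with partial eta squared.
    Includes a seeded synthetic-cohort generator (ramp-to-plateau
    efforts with physiological tremor and spike artifacts; sex-by-age
    strata with additive effects) so the full pipeline is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
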