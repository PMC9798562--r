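Package: angleguard
Title: Anterior Segment OCT Angle-Closure Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric grading of anterior segment optical coherence tomography
    (AS-OCT) anterior-chamber-angle cross sections from boundary-trace
    annotations, and the surrounding screening analytics for detecting eyes at
    high risk of angle closure (HRAC). Implements the trabecular-iris angle at
    750 um from the scleral spur (TIA750), the angle opening distance (AOD750),
    apposition detection, the preset 12-degree open/narrow/closed rule, iris
    configuration typing (flat, bowing, bombe, thick peripheral, mixed),
    eye-level HRAC aggregation over four quadrants, the screening exclusion
    cascade with full accounting, stratified prevalence tables with chi-square
    and t/Mann-Whitney comparisons, and a synthetic generator for both
    parametric angle geometry and screening cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
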