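Package: eegnetrel
Title: Test-Retest Reliability of EEG Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for assessing the test-retest reliability of
    sensor-space EEG functional networks across two recording sessions.
    Computes phase-based connectivity (phase lag index and debiased
    weighted phase lag index) from band-limited epochs, weighted graph
    characteristics (clustering coefficient, characteristic path length,
    small-worldness) with random-surrogate normalization, and three-level
    reliability statistics: per-subject matrix correlations, global and
    unit-wise intraclass correlations ICC(3,1), coefficients of variation,
    and bootstrap confidence intervals. Includes a synthetic two-session
    cohort generator with band-limited oscillatory coupling, subject
    connectivity fingerprints, and a tunable between-session stability
    parameter, so the full pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
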