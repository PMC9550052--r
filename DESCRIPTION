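Package: cardiocred
Title: Credibility Assessment Pipelines for Virtual Cohorts of Cardiac
    Electrophysiology Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the credibility of patient-specific cardiac
    electrophysiology simulations deployed as virtual cohorts. Provides a
    seeded synthetic-cohort generator (labeled tetrahedral ventricular slabs
    with scar, border zone, rule-based fibers and nested mesh resolutions),
    an anisotropic monodomain finite-element solver with a pluggable
    phenomenological cell model, extraction of activation/repolarization
    maps, pseudo-ECGs and high-repolarization-gradient volume (HRGV), a
    multi-patient mesh-convergence study with scaled-infinity-norm ECG error,
    cross-correlation lag and across-patient coefficients of variation, and a
    robustness battery (systematic-bias, worst-case, Monte-Carlo variant
    sampling, and normal conduction-velocity interpolation sampling) testing
    whether cohort-level conclusions survive uncertainty in border-zone
    extent and tissue conductivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
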