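Package: gatelag
Title: EPID-Based Beam Time Delay Quality Assurance for Respiratory-Gated
    Radiotherapy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures beam-on and beam-off time delays (latencies) of
    respiratory-gating systems from electronic portal imaging device (EPID)
    images of a moving high-contrast metal ball. Provides sub-pixel ball
    localisation by motion-axis profile analysis, conversion of detector-plane
    displacements to isocenter-plane delays through the projective
    magnification geometry, a trailing-edge matching algorithm for the
    motion-blurred beam-off trace, per-beam-mode and cross-energy summary
    statistics, and a seeded synthetic portal-image simulator so the full
    pipeline can be exercised and validated without a linac.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'gatelag-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'motion-model.R'
    'simulator.R'
    'ball-locator.R'
    'delay-analysis.R'
    'qa-report.R'
    'io.R'
    'config.R'
    'pipeline.R'
    'published-data.R'
    'show-methods.R'
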