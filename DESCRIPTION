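Package: kelpmech
Title: Biomechanics and Allometric Scaling of Bull Kelp Stipes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tensile biomechanics and allometric scaling
    of bull kelp (Nereocystis luetkeana) stipes across life stages. Extracts
    material properties (maximum stress, Young's modulus, extensibility,
    toughness, work to failure) from force-extension records of tensile tests,
    fits log-log scaling relationships by standard major axis (Model II)
    regression with analytic confidence intervals, classifies scaling against
    geometric null slopes, and estimates the isometry-to-allometry breakpoint
    by segmented regression with iterative linearization. Includes seeded
    synthetic-data generators with known ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
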