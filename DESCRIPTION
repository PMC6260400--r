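Package: ultrarhythm
Title: Model Selection for Circadian and Ultradian Harmonic Rhythms in
    Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies circadian (22 hr) and ultradian
    harmonic (11 hr, 7.33 hr) rhythms in gene-by-time expression matrices
    using cosinor harmonic regression with information-criterion model
    selection, F-test significance and Benjamini-Hochberg false discovery
    rate control.  Includes a time-label permutation null, a continuous
    period scan, correlation-based anti-phasic phase-group clustering,
    cross-genotype comparisons (circadian component subtraction, period
    reassignment tables, competitive gene-set tests, overlap enrichment),
    a synthetic time-course generator with genotype presets, and scoring
    of detection output against simulated ground truth.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
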