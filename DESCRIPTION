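Package: earlyamdrate
Title: OCT-Based Grading of Single Early-AMD Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements 'EarlyAMDRate', a grading instrument for single
    early age-related macular degeneration (AMD) lesions in spectral-domain
    OCT B-scans. Provides the structured grading questionnaire data model
    with validation and CSV/JSON round-trip, extraction and validation of
    colour lesion masks drawn over greyscale B-scans, lesion morphometrics
    (cutting area, projected diameter, centroid) in pixel and micrometre
    units, operational lesion-type classification (drusen, subretinal
    drusenoid deposits, hyper-reflective foci), leading-scan selection and
    longitudinal lesion tracking, cohort-level size statistics with
    log-normal distribution fitting and Shapiro-Wilk testing, and a fully
    seeded synthetic B-scan generator with ground-truth masks and grading
    records for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
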