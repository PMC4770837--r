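Package: vnaflow
Title: Batch Data Flow for Urinary Volatile Nitrosamine Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated sample data flow for isotope-dilution GC-MS/MS
    quantitation of six urinary volatile nitrosamines (NDMA, NMEA, NDEA,
    NPIP, NPYR, NMOR). Provides weighted least-squares calibration of
    response ratios against amount ratios, in-batch dichloromethane blank
    subtraction, per-sample quality-assurance rules (retention time,
    confirmation ion ratio, internal standard area, blank limits,
    carryover follow-up with tiered repeatability), Westgard multirule
    batch quality control, method-validation statistics (3*S0 and CLSI
    limits of detection, intra/inter-run precision, spike-recovery
    accuracy), a synthetic injection-data generator for 48-well plate
    batches, and worklist-to-sequence / LIMS-export plumbing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
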