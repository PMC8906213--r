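Package: filmtcm
Title: Temporal Calibration Models for Radiochromic Film Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-stamped dose-response calibrations ("temporal
    calibration models") for radiochromic film (GafChromic EBT3 and
    EBT-XD) from automated flatbed-scanner series, converts measurement
    film scans to absorbed dose at any postirradiation time, and
    quantifies the accuracy gain over a single fixed-time calibration
    with gamma-index analysis. Includes a film/scanner simulator that
    reproduces the logarithmic-in-time growth of net optical density,
    its dose and colour-channel dependence, and bounded scanner drift,
    so the full workflow can be validated end to end without physical
    film.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
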