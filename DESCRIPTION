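Package: ventzero
Title: Automated Detection of Mechanical Ventilation Onset in ICU Flowsheet Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for retrospectively identifying "time zero", the minute at
    which invasive mechanical ventilation began during an ICU stay, from
    electronic flowsheet extracts. Implements cohort filtering, screening of
    candidate charting variables (intubation note time, end-tidal CO2, peak
    inspiratory pressure, positive end-expiratory pressure) against a
    manual-review reference standard, PEEP-based onset detection with an
    optional note-anchored search window, and tolerance-band agreement
    statistics (percent agreement curves and kappa). Includes a synthetic
    electronic-medical-record generator that emulates the charting pathology
    of real ICU data marts, plus deterministic fixtures for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
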