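Package: oxival
Title: Pulse Oximeter Accuracy Validation Under Controlled Desaturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating pulse oximeter accuracy against arterial
    blood gas reference measurements in controlled-desaturation studies.
    Implements the Severinghaus oxygen dissociation model and a stepwise
    end-tidal oxygen (PetO2) desaturation protocol builder; a synthetic
    data generator producing paired SaO2/SpO2 measurement tables with
    saturation-dependent device bias, averaging-window lag, and
    missingness; the standard accuracy metrics (mean directional error,
    accuracy root-mean-square difference with bootstrap confidence
    intervals, missingness, error-band categorization); Bland-Altman
    analysis and saturation-binned accuracy profiles; occult hypoxemia
    detection; oxygen desaturation rate (ODR) stratification with
    participant-level paired testing; and FDA accuracy-threshold
    assessment, assembled into a reproducible validation report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
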