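Package: marie
Title: Multiple-Criteria Qualitative Value-Based Drug Pricing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a multiple-criteria qualitative value-based pricing
    framework for new drugs. Twelve value elements (four base, eight
    additional) are scored against fixed qualitative criteria; base points
    and the projected maximum number of patients are converted into a base
    daily price (JPY) through a conversion table defined by its 35-point
    anchor row, and a 2-percent-per-point premium for additional points
    yields the final daily price. Includes tools to rebuild the conversion
    table from drug-listing data (median daily listing price per patient
    category over a fiscal-year window), to compare table versions, and to
    generate synthetic listing datasets for testing the update pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
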