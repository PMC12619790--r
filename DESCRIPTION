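Package: bckpi
Title: Blood Culture Process Key Performance Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes quality key performance indicators (KPIs) for the
    hospital blood-culture process from de-identified bottle-level
    laboratory records. Groups bottles into sampling sets and 24-hour
    anchored episodes, classifies episodes (peripheral-vein versus
    intravascular-device, solitary, positive), applies a configurable
    contaminant-organism rule engine with restrictive criteria and a
    manual-review workflow, and reports blood volume, solitary-episode,
    unpaired-catheter-episode and contamination rates stratified by
    center, hospitalization area and hospital service. Includes a seeded
    synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
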