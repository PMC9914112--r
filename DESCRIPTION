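Package: msudbuddy
Title: Knowledge-Based Formula Dosing for Infants with Maple Syrup Urine Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ripple-down-rules (RDR) decision-support engine over a verified
    clinical-nutrition knowledge base for maple syrup urine disease (MSUD).
    Converts an infant's age, weight and plasma branched-chain amino acid
    (BCAA) panel plus a commercial/medical formula preference into a
    scoop-discretized daily feeding plan that never exceeds the leucine,
    isoleucine or valine allowance while targeting the protein, energy and
    fluid requirement. Includes a generic single-classification RDR engine
    with cornerstone-case preserving knowledge acquisition and JSON
    persistence, per-age per-kg allowance and formula-composition tables,
    patient-input validation with field-level error reporting, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
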