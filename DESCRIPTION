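Package: ipspipe
Title: Transform Korean Personal Health Record FHIR Exports into International Patient Summary Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic toolkit for converting FHIR R4 exports from the
    Korean "My Health Record" ecosystem into resources conformant with the
    International Patient Summary (IPS) implementation guide. Provides a
    machine-readable gap registry between the KR Core and IPS profile sets
    with coverage statistics, local-to-international terminology mapping
    (EDI and KCD to SNOMED CT) via packaged concept-map excerpts, a
    rule-based transformation engine for Immunization, Medication,
    MedicationRequest and Procedure resources, a two-tier (syntax and
    profile) validator, a seedable generator of realistic messy source
    data, and an extract-transform-load pipeline with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
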