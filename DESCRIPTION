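Package: seqbadge
Title: Tiered Badge Assessment of Sequence Data and Metadata Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of open-data compliance in microbiome
    publications. Detects INSDC accession numbers, PCR primer sequences,
    sequencing-method statements, code-availability links and
    data-availability-statement classes in article full text; assigns a
    tiered sequence-data availability badge (None, Bronze, Silver, Gold,
    or cannot-be-determined) from the assembled evidence; evaluates study
    metadata against tiered MIxS-derived checklists with attribute-name
    harmonization and cross-study sparsity analytics; and scores predicted
    badges against manual labels with accuracy, macro-average F1 and
    support-weighted F1. Includes a seeded synthetic corpus generator with
    known ground-truth badges and a fully offline fixture/replay layer so
    the whole pipeline is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
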