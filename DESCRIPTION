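Package: cerex
Title: Joint and Continual Entity-Relation Extraction for Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint biomedical information extraction that splits named-entity
    recognition into span detection (BIOES tagging) and entity typing, and
    couples both to relation extraction through entity-marker input
    augmentation. Classification uses expandable banks of one-vs-rest binary
    heads so the label vocabulary of entity and relation types can grow as new
    corpora arrive, and training follows continual, multi-corpora, or continual
    multi-corpora schedules over corpus subsets. Includes a token-level
    standoff corpus format, a synthetic-corpus generator emulating adverse
    drug event, drug-drug interaction and chemical-protein corpora, and a
    propagation-aware evaluation suite (span/type/relation micro-F1 with
    gold-conditioned variants isolating error cascades).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
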