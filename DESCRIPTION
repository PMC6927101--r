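Package: adrex
Title: Adverse Drug Reaction Extraction and MedDRA Normalization from Drug Labels
Version: 0.1.0
Authors@R:
    person("ADR", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for extracting adverse drug reaction (ADR)
    and related entity mentions from structured drug-label documents and
    normalizing ADRs to MedDRA Preferred Terms. Provides readers and writers
    for the TAC-style drug-label XML dialect and a 6-column CoNLL interchange
    format; offset-preserving sentence splitting, tokenization and BIO2
    encoding; a neural sequence tagger combining character-level
    convolutional features, word embeddings and casing features with stacked
    bidirectional LSTMs and a linear-chain CRF, trained with NADAM; a
    dictionary- and rule-based recognizer with term expansion; an LLT-to-PT
    normalizer; mention-level and micro/macro PT-level evaluation; and a
    seeded generator of synthetic annotated corpora and mini dictionaries so
    the whole pipeline is testable without restricted corpora or licensed
    terminologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    digest,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
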