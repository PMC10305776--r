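Package: strokener
Title: Clinical Named Entity Recognition for Thrombolysis Contraindication Surfacing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A toolkit for span-level named entity recognition (NER) in
    unstructured clinical letters, aimed at surfacing contraindications to
    thrombolysis in acute ischaemic stroke. Ships an 86-entity stroke
    ontology in five categories, brat standoff reading and writing, a
    deterministic offset-preserving tokenizer with an IOB tag codec, an
    exact string-search dictionary baseline, strict and lenient
    micro/macro span-matching evaluation, logit-averaging ensembling over
    pluggable token classifiers, per-label name-regularity and
    context-regularity statistics with a regression analysis linking label
    properties to per-label F1, and a synthetic annotated-letter simulator
    with an annotator-noise model and patient-level data splitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
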