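Package: listqa
Title: Multi-Span Extractive Question Answering via BIO Sequence Tagging
Version: 0.1.0
Authors@R: person("listqa", "developers", role = c("aut", "cre"),
    email = "listqa@example.org")
Description: Reformulates extractive question answering as multi-span
    sequence tagging. Converts question-passage-answer records in the
    BioASQ task-b JSON dialect (and SQuAD v1 for transfer pre-training)
    into BIO-labelled token sequences, trains a token tagger over a
    pluggable contextual encoder with masked supervision (linear, BiLSTM
    or BiLSTM-CRF heads with exact Viterbi inference), decodes a variable
    number of answers per question without probability thresholds or
    answer-count caps, and evaluates with BioASQ-style list metrics
    (macro precision/recall/F1) and factoid mean reciprocal rank. A
    synthetic corpus generator with planted, verifiable answer spans
    makes every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
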