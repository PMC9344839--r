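# listqa — multi-span extractive QA as BIO sequence tagging

Biomedical list-type questions ("Which genes are associated with …?") need a
*set* of answer phrases, but classic extractive QA models predict exactly one
span and recover multiplicity with fragile probability thresholds — a model
thresholding at probability *t* can never return more than ⌊1/*t*⌋ answers —
or with rule-based answer-count detection. `listqa` reformulates extractive
QA as **multi-span sequence tagging**: every token of a passage is labelled

```
B  (beginning of an answer span)   I  (inside)   O  (outside)
```

so one forward pass over one `[CLS] question [SEP] passage [SEP]` sequence
tags *all* answers at once, and the decoder returns exactly as many answers
as the tagger finds — no threshold, no cap. The package provides the whole
pipeline for R users working with BioASQ task-b style corpora:

* **corpus I/O** — BioASQ-dialect JSON (and SQuAD v1 for transfer
  pre-training), title+abstract passages, and the question-passage-answer
  sample construction rule: a question with *i* matchable passages and *j*
  answers yields *i·j* single-span samples but only *i* sequence-tagging
  samples; passages where no gold answer can be located are excluded.
* **annotation** — exact longest-leftmost answer matching over synonym
  groups, sub-word tokenization with character offsets, and masked BIO
  supervision (special tokens, question tokens and sub-word continuations
  are never penalized).
* **tagger** — a trainable context-window encoder behind a pluggable
  encoder contract, with linear, BiLSTM, or BiLSTM-CRF heads; masked
  cross-entropy or exact CRF likelihood (forward algorithm), Viterbi
  decoding, Adam, per-epoch reshuffling, full determinism from one seed.
* **decoding** — offset-based detokenization (candidates are literal
  passage substrings, so sub-words and punctuation spacing are exact by
  construction), per-candidate confidence (softmax mean or CRF span
  marginal), cross-passage aggregation with deduplication.
* **evaluation** — BioASQ-style macro list precision/recall/F1 (one-to-one
  prediction–group matching), factoid MRR@k, the predicted-vs-gold
  answer-count histogram (bin width 2, zero-answer questions excluded), and
  a number-in-question detector.
* **synthetic** — a deterministic generator that plants a controllable
  number of multi-word pseudo-entity answers (with optional synonyms and
  hard-mode distractor embeddings) verbatim into distractor-laden passages,
  with white-box ground truth, so everything above is testable offline.

## Worked example

Train on 200 synthetic list questions, evaluate on 50 held-out questions
whose answer entities were never seen in training:

```r
library(listqa)

g <- generate_synthetic(synthetic_spec(
  n_questions = 250, answers_per_question = 1:4, seed = 11))
refs  <- function(qs) unlist(lapply(qs, `[[`, "passage_refs"))
train <- qa_corpus(g$corpus$questions[1:200],
                   unname(g$corpus$passages[refs(g$corpus$questions[1:200])]))
test  <- qa_corpus(g$corpus$questions[201:250],
                   unname(g$corpus$passages[refs(g$corpus$questions[201:250])]))

tk    <- word_tokenizer()
model <- fit_span_tagger(train,
  train_config(head = "linear", lr = 0.05, max_steps = 400, seed = 3), tk)
model
#> <span_tagger> head=linear vocab=390 dim=16x(2*1+1) steps=400 final loss=0.03824

q <- test$questions[[1]]
q$body
#> "Which genes are associated with Lurufa?"
predict_question(model, q, test$passages, tk)
#> <question_prediction> synq0201: 4 answer(s)
#>   1. pofalosi dofikemi tififi (0.996)
#>   2. tirofu donudene napeza (0.983)
#>   3. fidi vogagu dadifi (0.905)
#>   4. zulonagi gurefu sugisavi (0.852)

preds <- predict_corpus(model, test, tk)
eval_list(preds, test)
#> <list_eval> 50 questions  macro P=0.9140 R=0.9300 F1=0.9210

answer_count_report(preds, test)$modal_bin_predicted
#> 1   # matches the gold modal bin: the tagger learns *how many* answers
```

The four answers above are exactly the question's four gold phrases — the
model ranked and returned a variable-size answer set with no threshold. The
macro scores are the unweighted means over questions of per-question
precision/recall/F1 under one-to-one exact matching against synonym groups.

A two-stage transfer schedule is two calls: fit on a SQuAD-mapped corpus
(`read_squad()`, conventionally at learning rate 5e-5), then pass that model
as `init_model` when fitting on the target corpus (default rate 5e-6).

## Command line

```sh
Rscript inst/cli/convert.R --input corpus.json --format bioasq \
        --config seq_tag --output samples.json
```

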