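---
title: "Multi-span extractive QA by sequence tagging: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-span extractive QA by sequence tagging: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listqa)
```

## The model

Extractive question answering is usually framed as predicting one start and
one end index per question–passage pair. List-type questions break that
frame: their answer is a *set* of phrases, and single-span models recover
multiplicity only through post-hoc devices — a probability threshold $t$
(which structurally caps the answer count at $\lfloor 1/t\rfloor$, because
kept probabilities each exceed $t$ and sum to at most 1) or a rule that
detects a number in the question and emits exactly that many answers.

`listqa` instead treats the task as token-level sequence labelling. The
input sequence is

$$[\mathrm{CLS}]\; q_1 \dots q_m\; [\mathrm{SEP}]\; p_1 \dots p_n\; [\mathrm{SEP}]$$

and each token receives one of three labels under the BIO scheme: `B` opens
an answer span, `I` continues it, `O` is background. Adjacent answers are
separated by a fresh `B`. A passage with $k$ planted answers is one training
sample with $k$ `B` runs — not $k$ separate samples — which is exactly the
$i$ vs $i \cdot j$ sample-count distinction between the sequence-tagging and
single-span configurations that `build_samples()` implements. Passages in
which no gold answer string can be located are excluded from training.

Per-token scores come from a pluggable encoder followed by one of three
heads:

* **linear** — an affine map of each token representation to the three
  label scores;
* **BiLSTM** — a bidirectional LSTM over the sequence, then the affine map;
* **BiLSTM-CRF** — BiLSTM scores used as unary potentials of a linear-chain
  conditional random field with a learned $3\times 3$ transition matrix and
  start/end scores, trained by exact path log-likelihood (forward algorithm
  in log space) and decoded with Viterbi.

### Supervision masking

Only word-initial passage tokens carry supervision. Special tokens, question
tokens and sub-word continuation pieces are labelled `IGNORE`; they
contribute exactly zero loss and zero gradient, so the model is never
penalized for whatever it predicts there. The mask is stored *in-band* as
the reserved `IGNORE` label, so the masking contract is tested as: arbitrary
perturbation of the scores at ignored positions leaves the loss bit-for-bit
unchanged, and the gradient there is identically zero.

The CRF is the exception, because a path likelihood needs a label at every
position. Two behaviours are provided (`crf_ignore` in `train_config()`):

* `"as_o"` (default): ignored positions are trained as `O` — the
  conventional treatment when a CRF layer is attached, where special-token
  exclusion is not applied;
* `"marginalize"`: true masking — the objective is the marginal likelihood
  of the supervised labels, summing over all labelings of ignored positions
  (one constrained and one unconstrained forward pass; the gradient is the
  difference of the two expectation vectors). This is the mathematically
  clean reading of "don't penalize these positions" and is verified against
  exhaustive enumeration in the tests.

### Decoding

At inference the predicted labels over word-initial passage tokens are
segmented into maximal `B I*` runs; an `I` with no open run is repaired to
`B` (the truth table for all short label strings is pinned in the tests).
Each run becomes a character span from its first token's start offset to the
end of its last token's *word* (continuation pieces inherit membership).
The answer text is the literal passage substring at those offsets — this is
the package's central representation decision: because spans carry original
character coordinates, "detokenization" (sub-word merging, whitespace around
punctuation) is exact by construction rather than a heuristic string join.

Candidates from all of a question's passages are concatenated, deduplicated
by normalized text (lower-case, trim, collapse whitespace) keeping the best
score, and ranked by score. Confidence is the mean softmax probability of
the decoded labels over the span (linear/BiLSTM) or the CRF marginal
probability of the span labelling, i.e. the ratio of a constrained to the
unconstrained partition. The answer list is never truncated: returning
seven answers when the tagger finds seven is the point. A
`threshold_filter()` utility reproduces the thresholding baseline — and its
$\lfloor 1/t \rfloor$ bound — for comparison only.

## The encoder

No deep-learning runtime is assumed. The encoder contract is a
deterministic map from a tokenized input to one fixed-width vector per
token; heavyweight pretrained biomedical transformers satisfy it but live
outside this package. The in-package encoder represents token $t$ by the
concatenation of trainable embeddings of tokens $t-w,\dots,t+w$
(`window_encoder()`), which keeps the entire model trainable in seconds on
one CPU while still being contextual: in the synthetic world the evidence
that a token begins an answer is carried by its neighbours (a cue word, a
comma, a conjunction), not by the token's own identity.

Two standard devices make the encoder generalize to answer entities never
seen in training:

* **vocabulary pruning** (`vocab_min_count`, default 3): tokens rarer than
  the cutoff in the training corpus train as the unknown token — which is
  precisely how unseen words present at prediction time;
* **word dropout** (`word_dropout`, default 0.1): tokens are randomly
  replaced by the unknown id during training, further training the unknown
  embedding in context.

Without these, the tagger memorizes entity identities and held-out F1
collapses (~0.3 in our ablation); with them the same model exceeds 0.9.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `batch_size` | 18 | minibatch size (reference fine-tuning setup) |
| `lr` | 5e-6 | target-stage learning rate; the transfer stage conventionally uses 5e-5; the from-scratch tiny encoder needs ~0.05 |
| `max_len` | 512 tokens | input cap; passages are tail-truncated, questions never |
| `dim`, `window` | 16, 1 | embedding width and context half-width |
| `hidden` | 16 | BiLSTM units per direction |
| `vocab_min_count` | 3 | vocabulary pruning threshold (tokens) |
| `word_dropout` | 0.1 | unknown-token replacement probability (training only) |
| `clip` | 5 | global gradient-norm clip |
| `seed` | — | drives initialization, shuffling and dropout; recorded in the model |

The 5e-6/5e-5/18/512 defaults mirror the reference configuration for
fine-tuning pretrained encoders and are kept as defaults even though the
in-package encoder trains from scratch; tests pass an explicit rate.
Training shuffles sample order at the start of every epoch, uses Adam, and
aborts with a diagnostic on non-finite loss. Two runs from the same seed,
config and data produce identical logs.

## The synthetic world

`generate_synthetic()` emulates the regime that motivates multi-span QA:
list questions with several answers. Each question draws $k$ answers
(uniform over `answers_per_question`, default 1–4, matching the observation
that most list questions need a handful of phrases); each answer is a 2–3
word pseudo-entity planted verbatim in a carrier sentence of every linked
title+abstract passage, surrounded by a lead sentence and distractor
sentences mentioning unrelated entities of identical surface shape. Planting
positions are emitted as white-box ground truth, and `plant_check()`
verifies both the slices and the empirical answer-count distribution
(exactly for a point mass, within three standard errors otherwise).

Defaults chosen once, and why:

* **`synonym_prob = 0`** — synonym variants (planted abbreviations) are
  opt-in. A planted synonym makes the exact-match metric's ceiling less
  than 1 *by construction*: a perfect tagger predicts both surface forms,
  and under one-to-one matching the second is a false positive. Synonyms
  therefore serve as an explicit stressor for the matching and evaluation
  code paths, not as part of the base world.
* **2–3-word answers** with a 6-character sub-word cap, so multi-token
  spans and continuation masking are always exercised.
* **`hard_mode`** embeds some answers verbatim inside distractor sentences
  (extra true occurrences in misleading contexts, recorded in the truth).

What a green learnability test establishes: the pipeline can learn, from
200 questions, to tag a *variable number* of previously unseen multi-word
entities per passage with macro F1 ≥ 0.9, and the predicted answer-count
distribution has the same modal bin as the gold one. What it does not
establish: performance on real biomedical prose — real passages have
paraphrase, anaphora, nested entities and annotation noise that the
generator deliberately does not model, and real encoders are pretrained
transformers, not context windows.

## Numerical choices and degenerate inputs

* All lattice computations are in log space; the CRF partition is exact and
  is tested against exhaustive path enumeration to 1e-9 relative error, the
  gradients against central finite differences.
* Viterbi ties are broken deterministically by backtracking with
  lowest-label-index preference, which prefers the lower label index at the
  latest differing position; an all-zero instance decodes to `B B … B`.
* Character coordinates are 1-based inclusive (`substr` convention)
  throughout.
* Answer matching is exact substring search, word-boundary-agnostic, with
  longest-leftmost overlap resolution; uncased matching lower-cases both
  sides but reports original coordinates.
* Degenerate inputs fail loudly: a question longer than `max_len − 3`
  tokens, a passage with no room after truncation, both title and abstract
  empty, overlapping spans passed to the labeller, an all-`IGNORE` sample,
  non-finite scores, out-of-range spans at detokenization.
* Spans lost beyond the 512-token truncation window are dropped with a
  warning and are unrecoverable by design.

## Open design points, decided

* **Passage text** is `title + " " + abstract` (the join rule is not
  dictated by the dialect; it is recorded here and in `build_passage_text()`
  so alternative dialects can adapt).
* **Single-span expansion** enumerates (passage, synonym *group*) pairs
  using the group's first matching occurrence, reproducing the $i \cdot j$
  count with $j$ = number of answers; per-variant expansion is available as
  `expand_variants = TRUE`.
* **All occurrences** of an answer are tagged, not only the first:
  multi-occurrence tagging maximizes supervision and is the natural
  sequence-labelling reading.
* **Transitions are unconstrained** by default (`O → I` is learnable);
  decoding repairs orphan `I`, and a `strict_transitions` switch clamps the
  forbidden transitions to $-\infty$ for users who prefer hard constraints.
* **Evaluation matching** is maximum bipartite matching (augmenting paths)
  between predictions and synonym groups, so a prediction never blocks a
  group another prediction could have taken; with disjoint groups this
  reduces to the obvious greedy count.

## Known limitations

Tail-only truncation (no sliding windows); no yes/no or summary question
handling; no live retrieval of passages (text must be inline); the
in-package encoder is a testing-scale stand-in, and reported synthetic
scores say nothing quantitative about real-corpus performance. The
evaluation module is an independent reimplementation of the challenge
metrics; `export_submission()` writes predictions in the challenge JSON
shape so the official scorers can be applied externally.
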