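# Tag sequences -> answer strings. Candidate text is recovered by slicing
# the original passage at character offsets, never by re-joining token
# strings, so sub-word reconstruction and punctuation spacing are exact by
# construction. No probability threshold and no answer-count cap anywhere.

#' Convert a label sequence to character spans
#'
#' Operates on the word-initial passage tokens (the decoded positions).
#' Each maximal run starting with `B` and continuing through `I` yields one
#' span from the run's first token start offset to its last token end
#' offset; an `I` with no open run is repaired to `B` and opens a new span.
#' Sub-word continuation pieces inherit the membership of the word they
#' complete, so a span's end offset extends through the trailing
#' continuation pieces of its last word.
#'
#' @param labels Character labels aligned to `tokenized$tokens`; positions
#'   other than word-initial passage tokens are ignored (an `IGNORE` there
#'   is treated as `O`).
#' @param tokenized The `tokenized_input` the labels refer to.
#' @return Data frame of `start`, `end` (1-based inclusive passage
#'   coordinates); zero rows when no span is tagged.
#' @export
labels_to_spans <- function(labels, tokenized) {
  stopifnot(inherits(tokenized, "tokenized_input"),
            length(labels) == length(tokenized$tokens))
  sup <- supervised_positions(tokenized)
  word_end <- function(pos) {
    # extend through continuation pieces of the word starting at pos
    e <- tokenized$end[pos]
    k <- pos + 1L
    while (k <= length(tokenized$tokens) &&
           tokenized$origin[k] == "passage" && tokenized$continuation[k]) {
      e <- tokenized$end[k]
      k <- k + 1L
    }
    e
  }
  starts <- integer(); ends <- integer(); open <- FALSE
  cur_start <- NA_integer_; cur_end <- NA_integer_
  for (pos in sup) {
    lab <- labels[pos]
    if (lab == "B" || (lab == "I" && !open)) {      # orphan-I repair
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur_end) }
      open <- TRUE
      cur_start <- tokenized$start[pos]
      cur_end <- word_end(pos)
    } else if (lab == "I") {
      cur_end <- word_end(pos)
    } else {                                        # O or IGNORE closes
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur_end) }
      open <- FALSE
    }
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur_end) }
  data.frame(start = starts, end = ends)
}

#' Recover the answer string for a span
#'
#' The literal passage substring at the span's character offsets. Because
#' spans carry original coordinates, sub-word merging and whitespace around
#' punctuation are restored exactly.
#'
#' @param span A list or one-row data frame with `start` and `end`.
#' @param passage_text The passage string the span indexes.
#' @return The answer string.
#' @export
detokenize <- function(span, passage_text) {
  s <- as.integer(span$start); e <- as.integer(span$end)
  if (length(s) != 1L || length(e) != 1L || s < 1L || e > nchar(passage_text) ||
      s > e)
    stop("span [", span$start, ",", span$end, "] out of range for passage of ",
         nchar(passage_text), " characters")
  substr(passage_text, s, e)
}

#' Confidence score of a decoded candidate
#'
#' For the linear/BiLSTM heads: the mean per-token softmax probability of
#' the decoded `B`/`I` labels over the span's word-initial tokens. For the
#' CRF head: the marginal probability of the span's labelling (the ratio of
#' the constrained to the unconstrained partition, via the forward
#' recursion).
#'
#' @param span A span (`start`, `end`) in passage coordinates.
#' @param scores L x 3 token score matrix for the full input sequence.
#' @param tokenized The `tokenized_input` the scores align to.
#' @param method `"softmax"` (linear/BiLSTM rule) or `"crf"`.
#' @param transitions CRF transitions, required for `method = "crf"`.
#' @return A probability-like score in `[0, 1]`.
#' @export
score_candidate <- function(span, scores, tokenized,
                            method = c("softmax", "crf"), transitions = NULL) {
  method <- match.arg(method)
  sup <- supervised_positions(tokenized)
  pos <- sup[!is.na(tokenized$start[sup]) &
             tokenized$start[sup] >= span$start &
             tokenized$start[sup] <= span$end]
  if (length(pos) == 0L) return(0)
  span_labels <- c("B", rep("I", length(pos) - 1L))
  if (method == "softmax") {
    P <- softmax_rows(scores[pos, , drop = FALSE])
    return(mean(P[cbind(seq_along(pos), match(span_labels, BIO_LABELS))]))
  }
  crf_span_marginal(scores, transitions, pos, span_labels)
}

normalize_answer <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Aggregate per-passage candidates into a question prediction
#'
#' Simple concatenation of the candidates decoded from every passage of the
#' question, deduplicated by normalized text (lower-case, trimmed, internal
#' whitespace collapsed) keeping the maximum score, then sorted by score
#' descending with first-seen order breaking ties. The answer list is never
#' truncated to a fixed count: the model predicts as many answers as it
#' needs.
#'
#' @param question_id Question identifier.
#' @param candidates Data frame with columns `text`, `score`, `passage_id`
#'   (zero rows allowed: an empty answer list is a valid prediction).
#' @return A `question_prediction`: list with `question_id` and `answers`
#'   (data frame `text`, `score`, `passage_id`).
#' @export
aggregate_candidates <- function(question_id, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    answers <- data.frame(text = character(), score = numeric(),
                          passage_id = character())
  } else {
    key <- normalize_answer(candidates$text)
    best <- vapply(split(seq_len(nrow(candidates)), key)[unique(key)],
                   function(ix) ix[which.max(candidates$score[ix])], 0L)
    answers <- candidates[best, , drop = FALSE]
    answers <- answers[order(-answers$score, seq_len(nrow(answers))), ,
                       drop = FALSE]
    rownames(answers) <- NULL
  }
  structure(list(question_id = question_id, answers = answers),
            class = "question_prediction")
}

#' @export
print.question_prediction <- function(x, ...) {
  cat("<question_prediction> ", x$question_id, ": ", nrow(x$answers),
      " answer(s)\n", sep = "")
  if (nrow(x$answers) > 0L)
    cat(paste0("  ", format(seq_len(nrow(x$answers))), ". ",
               x$answers$text, " (", signif(x$answers$score, 3), ")",
               collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Post-hoc probability-threshold filter (comparison utility)
#'
#' Reproduces the behaviour of thresholding baselines for comparison only:
#' candidate scores are normalized to a probability distribution and
#' answers with probability below `t` are dropped. Since the kept
#' probabilities each exceed `t` and sum to at most 1, at most `floor(1/t)`
#' answers can survive -- the structural bound on every thresholding
#' system. The native decoder never applies this filter.
#'
#' @param prediction A `question_prediction`.
#' @param t Probability threshold in (0, 1].
#' @return A filtered `question_prediction`.
#' @export
threshold_filter <- function(prediction, t) {
  stopifnot(inherits(prediction, "question_prediction"), t > 0, t <= 1)
  a <- prediction$answers
  if (nrow(a) > 0L) {
    p <- a$score / sum(a$score)
    a <- a[p >= t, , drop = FALSE]
    rownames(a) <- NULL
  }
  structure(list(question_id = prediction$question_id, answers = a),
            class = "question_prediction")
}

# ---- model prediction pipeline ---------------------------------------------

# Predict a full label sequence for one tokenized input.
predict_tags <- function(model, tokenized) {
  ids <- encoder_ids(model$encoder, tokenized$tokens, train = FALSE)
  X <- encoder_forward(model$encoder, ids)$X
  S <- score_tokens(X, model$head)
  if (!is.null(model$transitions)) {
    path <- viterbi_decode(S, model$transitions)$path
  } else {
    path <- BIO_LABELS[max.col(S, ties.method = "first")]
  }
  list(labels = path, scores = S)
}

#' Predict the answers for one question
#'
#' Runs the fitted tagger over every passage of the question, decodes tag
#' runs to character spans, slices the passage text, scores each candidate,
#' and aggregates across passages with [aggregate_candidates()].
#'
#' @param model A fitted [train_tagger()] model.
#' @param question A `qa_question`.
#' @param passages Named list of `qa_passage` objects (e.g.
#'   `corpus$passages`).
#' @param tokenizer The [word_tokenizer()] used at training time.
#' @return A `question_prediction`.
#' @export
predict_question <- function(model, question, passages, tokenizer) {
  cands <- data.frame(text = character(), score = numeric(),
                      passage_id = character())
  method <- if (is.null(model$transitions)) "softmax" else "crf"
  for (pid in question$passage_refs) {
    p <- passages[[pid]]
    if (is.null(p)) stop("unknown passage '", pid, "'")
    tok <- tokenize_and_pack(question$body, p$text, tokenizer,
                             max_len = model$config$max_len)
    pr <- predict_tags(model, tok)
    spans <- labels_to_spans(pr$labels, tok)
    for (i in seq_len(nrow(spans))) {
      sp <- spans[i, ]
      cands <- rbind(cands, data.frame(
        text = detokenize(sp, p$text),
        score = score_candidate(sp, pr$scores, tok, method = method,
                                transitions = model$transitions),
        passage_id = pid))
    }
  }
  aggregate_candidates(question$question_id, cands)
}

#' Predict answers for every supported question of a corpus
#'
#' @param model A fitted [train_tagger()] model.
#' @param corpus A `qa_corpus`.
#' @param tokenizer The [word_tokenizer()] used at training time.
#' @param types Question types to predict for (default factoid and list).
#' @return Named list of `question_prediction` objects, keyed by
#'   question id.
#' @export
predict_corpus <- function(model, corpus, tokenizer,
                           types = c("factoid", "list")) {
  qs <- Filter(function(q) q$qtype %in% types, corpus$questions)
  preds <- lapply(qs, predict_question, model = model,
                  passages = corpus$passages, tokenizer = tokenizer)
  names(preds) <- vapply(qs, `[[`, "", "question_id")
  preds
}
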