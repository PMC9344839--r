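# BioASQ-style evaluation: macro list precision/recall/F1, factoid MRR,
# and the answer-count / number-in-question analyses. The metrics are an
# independent reimplementation of the challenge scoring (the official
# scripts are not vendored); export_submission() writes predictions in the
# challenge submission shape for external cross-checks.

#' Exact-match comparison against a synonym group
#'
#' True iff the normalized prediction (lower-case, trimmed, internal
#' whitespace collapsed) equals any normalized variant of the group. Exact
#' equality, not substring containment.
#'
#' @param prediction_text Predicted answer string.
#' @param group Character vector of synonym variants.
#' @return Logical scalar.
#' @export
match_answer <- function(prediction_text, group) {
  normalize_answer(prediction_text) %in% normalize_answer(group)
}

pred_texts <- function(p) {
  if (inherits(p, "question_prediction")) p$answers$text else as.character(p)
}

# One-to-one matching between predictions and gold groups: maximum bipartite
# matching by augmenting paths (Kuhn's algorithm), so a prediction never
# blocks a group another prediction could have taken.
match_counts <- function(preds, groups) {
  if (length(preds) == 0L || length(groups) == 0L) return(0L)
  edge <- vapply(groups, function(g)
    vapply(preds, match_answer, group = g, FUN.VALUE = TRUE),
    FUN.VALUE = logical(length(preds)))
  edge <- matrix(edge, nrow = length(preds))
  owner <- rep(NA_integer_, length(groups))   # group -> prediction
  visited <- logical(length(groups))
  augment <- function(i) {
    for (j in which(edge[i, ] & !visited)) {
      visited[j] <<- TRUE
      if (is.na(owner[j]) || augment(owner[j])) {
        owner[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_along(preds)) {
    visited <- logical(length(groups))
    if (augment(i)) tp <- tp + 1L
  }
  tp
}

#' Evaluate list-question predictions
#'
#' Per question: each gold synonym group may be matched by at most one
#' prediction; TP is the number of matched groups, precision TP divided by
#' the number of predictions (0 when there are none), recall TP divided by
#' the number of groups, F1 their harmonic mean (0 when P + R = 0). The
#' summary scores are unweighted arithmetic means over questions
#' (macro-averaging).
#'
#' @param predictions Named list (by question id) of `question_prediction`
#'   objects or plain character vectors of answer strings.
#' @param corpus A `qa_corpus` (or list of `qa_question`) holding the gold
#'   standard; only list-type questions are evaluated.
#' @return A `list_eval` object: `per_question` data frame
#'   (`question_id`, `precision`, `recall`, `f1`), macro means, and the
#'   number of evaluated questions.
#' @export
eval_list <- function(predictions, corpus) {
  questions <- if (inherits(corpus, "qa_corpus")) corpus$questions else corpus
  gold <- Filter(function(q) q$qtype == "list", questions)
  gold_ids <- vapply(gold, `[[`, "", "question_id")
  unknown <- setdiff(names(predictions), gold_ids)
  if (length(unknown) > 0L)
    stop("predictions for unknown or non-list question id(s): ",
         paste(unknown, collapse = ", "))
  qid <- character(); P <- numeric(); R <- numeric(); F1 <- numeric()
  for (q in gold) {
    preds <- pred_texts(predictions[[q$question_id]])
    tp <- match_counts(preds, q$gold_answers)
    p <- if (length(preds) == 0L) 0 else tp / length(preds)
    r <- tp / length(q$gold_answers)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    qid <- c(qid, q$question_id); P <- c(P, p); R <- c(R, r); F1 <- c(F1, f)
  }
  structure(list(per_question = data.frame(question_id = qid, precision = P,
                                           recall = R, f1 = F1),
                 macro_precision = mean(P), macro_recall = mean(R),
                 macro_f1 = mean(F1), n_questions = length(qid)),
            class = "list_eval")
}

#' @export
print.list_eval <- function(x, ...) {
  cat(sprintf("<list_eval> %d questions  macro P=%.4f R=%.4f F1=%.4f\n",
              x$n_questions, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Mean reciprocal rank for factoid questions
#'
#' Per question: 1/rank of the first correct candidate within the top `k`
#' ranked predictions, 0 if none is correct there; averaged over questions.
#'
#' @param predictions As in [eval_list()].
#' @param corpus Gold standard; only factoid questions are evaluated.
#' @param k Rank cap (default 5, the challenge convention).
#' @return A `factoid_eval` object with `mrr`, `per_question` and
#'   `n_questions`.
#' @export
eval_factoid_mrr <- function(predictions, corpus, k = 5L) {
  questions <- if (inherits(corpus, "qa_corpus")) corpus$questions else corpus
  gold <- Filter(function(q) q$qtype == "factoid", questions)
  gold_ids <- vapply(gold, `[[`, "", "question_id")
  unknown <- setdiff(names(predictions), gold_ids)
  if (length(unknown) > 0L)
    stop("predictions for unknown or non-factoid question id(s): ",
         paste(unknown, collapse = ", "))
  qid <- character(); rr <- numeric()
  for (q in gold) {
    preds <- utils::head(pred_texts(predictions[[q$question_id]]), k)
    hit <- which(vapply(preds, match_answer, group = q$gold_answers[[1L]],
                        FUN.VALUE = TRUE))
    qid <- c(qid, q$question_id)
    rr <- c(rr, if (length(hit) == 0L) 0 else 1 / hit[1L])
  }
  structure(list(mrr = mean(rr),
                 per_question = data.frame(question_id = qid,
                                           reciprocal_rank = rr),
                 n_questions = length(qid)),
            class = "factoid_eval")
}

#' Answer-count distribution report
#'
#' Histograms of the number of predicted and of gold answers per question,
#' with half-open bins of width `bin_width` starting at 1 (`[1,3)`,
#' `[3,5)`, ...). Questions with zero predicted answers are excluded from
#' the predicted histogram and reported separately; bin populations
#' therefore sum to the number of questions with at least one answer.
#'
#' @param predictions As in [eval_list()] (list questions).
#' @param corpus Gold standard.
#' @param bin_width Bin width (default 2).
#' @return A `distribution_report`: `predicted` and `gold` histograms
#'   (data frames `bin_start`, `bin_end`, `count`), the zero-answer
#'   exclusion counts, and the modal bin start of each histogram.
#' @export
answer_count_report <- function(predictions, corpus, bin_width = 2L) {
  questions <- if (inherits(corpus, "qa_corpus")) corpus$questions else corpus
  gold <- Filter(function(q) q$qtype == "list", questions)
  pred_n <- vapply(gold, function(q)
    length(pred_texts(predictions[[q$question_id]])), 0L)
  gold_n <- vapply(gold, function(q) length(q$gold_answers), 0L)
  bin_up <- function(counts) {
    counts <- counts[counts >= 1L]
    if (length(counts) == 0L)
      return(data.frame(bin_start = integer(), bin_end = integer(),
                        count = integer()))
    starts <- seq.int(1L, max(counts), by = bin_width)
    data.frame(bin_start = starts, bin_end = starts + bin_width,
               count = vapply(starts, function(s)
                 sum(counts >= s & counts < s + bin_width), 0L))
  }
  ph <- bin_up(pred_n); gh <- bin_up(gold_n)
  modal <- function(h) if (nrow(h) == 0L) NA_integer_
                       else h$bin_start[which.max(h$count)]
  structure(list(predicted = ph, gold = gh,
                 excluded_zero_predicted = sum(pred_n == 0L),
                 excluded_zero_gold = sum(gold_n == 0L),
                 modal_bin_predicted = modal(ph), modal_bin_gold = modal(gh)),
            class = "distribution_report")
}

SPELLED_CARDINALS <- c("one", "two", "three", "four", "five", "six", "seven",
                       "eight", "nine", "ten", "eleven", "twelve", "thirteen",
                       "fourteen", "fifteen", "sixteen", "seventeen",
                       "eighteen", "nineteen", "twenty")

#' Does a question mention a number of answers?
#'
#' Analysis utility for the number-in-question phenomenon: rule-based
#' systems detect a number in the question (e.g. "What 2 biological
#' processes are regulated by STAMP2 in adipocytes?") and output exactly
#' that many answers. True iff the text contains a digit or a spelled-out
#' cardinal from the closed list one..twenty (word-bounded,
#' case-insensitive).
#'
#' @param question_text Question string.
#' @return Logical scalar.
#' @export
question_contains_number <- function(question_text) {
  if (grepl("[0-9]", question_text)) return(TRUE)
  grepl(paste0("\\b(", paste(SPELLED_CARDINALS, collapse = "|"), ")\\b"),
        tolower(question_text))
}

#' Export predictions in the challenge submission shape
#'
#' Writes a `{"questions": [{"id", "type", "exact_answer"}]}` JSON document
#' (list answers as an array of single-variant arrays, factoid as a flat
#' array) so external official scorers can be applied.
#'
#' @param predictions Named list of `question_prediction` objects.
#' @param corpus The `qa_corpus` supplying question types.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_submission <- function(predictions, corpus, path) {
  qtypes <- stats::setNames(vapply(corpus$questions, `[[`, "", "qtype"),
                            vapply(corpus$questions, `[[`, "", "question_id"))
  qs <- lapply(names(predictions), function(qid) {
    texts <- pred_texts(predictions[[qid]])
    ea <- if (identical(qtypes[[qid]], "list")) lapply(texts, list)
          else as.list(texts)
    list(id = qid, type = qtypes[[qid]], exact_answer = ea)
  })
  jsonlite::write_json(list(questions = qs), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
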