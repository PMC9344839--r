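# Synthetic BioASQ-dialect corpora with planted, verifiable answer spans.
# The generator emulates the dominant regime of biomedical list questions --
# several answer phrases per question, planted verbatim in title+abstract
# passages among distractor sentences -- so every module is testable and
# learnability measurable without any download. Ground-truth spans are
# emitted alongside the corpus for white-box tests.

SYN_CONSONANTS <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                    "t", "v", "z")
SYN_VOWELS <- c("a", "e", "i", "o", "u")
SYN_CATEGORIES <- c("proteins", "genes", "drugs", "enzymes", "factors")
# words used by the sentence templates; pseudo-words must avoid them
SYN_TEMPLATE_WORDS <- c("which", "are", "associated", "with", "the", "a",
                        "study", "of", "recent", "work", "has", "examined",
                        "in", "several", "models", "earlier", "reports",
                        "described", "unrelated", "settings", "and", "term",
                        "is", "used", "interchangeably", SYN_CATEGORIES)

syn_word <- function(min_syll = 2L, max_syll = 4L) {
  repeat {
    n <- sample(min_syll:max_syll, 1L)
    w <- paste0(paste0(sample(SYN_CONSONANTS, n, replace = TRUE),
                       sample(SYN_VOWELS, n, replace = TRUE)), collapse = "")
    if (!w %in% SYN_TEMPLATE_WORDS) return(w)
  }
}

syn_entity <- function(n_words) {
  paste(vapply(seq_len(n_words), function(i) syn_word(), ""), collapse = " ")
}

#' Declare a synthetic corpus
#'
#' @param n_questions Number of list questions.
#' @param answers_per_question Integer vector: the number of gold answers
#'   per question is drawn uniformly from it (a scalar is a point mass).
#'   Default `1:4`.
#' @param passages_per_question Passages linked to each question; every
#'   passage carries all of the question's answers. Default 1.
#' @param n_distractors Distractor sentences per passage. Default 2.
#' @param distractor_vocab Size of the shared distractor-entity vocabulary;
#'   must be at least `n_distractors` (sampling per passage is without
#'   replacement). Default 40.
#' @param synonym_prob Probability that an answer group carries a second
#'   surface variant (an abbreviation), also planted in the passage.
#'   Default 0: synonyms are an opt-in stressor, because a planted synonym
#'   makes the exact-match list metric's ceiling less than 1 by
#'   construction (a perfect tagger predicts both surface forms and the
#'   second counts as a false positive).
#' @param hard_mode If `TRUE`, some answers are additionally embedded
#'   verbatim inside distractor sentences (extra true occurrences in
#'   misleading contexts, recorded in the emitted truth). Default `FALSE`.
#' @param answer_words Range of words per answer phrase (default `2:3`, so
#'   sub-word and multi-token code paths are exercised).
#' @param seed Mandatory random seed; generation is fully deterministic
#'   given the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_questions, answers_per_question = 1:4,
                           passages_per_question = 1L, n_distractors = 2L,
                           distractor_vocab = 40L, synonym_prob = 0,
                           hard_mode = FALSE, answer_words = 2:3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_questions >= 1L, all(answers_per_question >= 1L),
            passages_per_question >= 1L, n_distractors >= 0L,
            synonym_prob >= 0, synonym_prob <= 1, all(answer_words >= 1L))
  if (distractor_vocab < n_distractors)
    stop("distractor vocabulary (", distractor_vocab,
         ") too small for ", n_distractors, " distinct distractors per passage")
  structure(list(n_questions = as.integer(n_questions),
                 answers_per_question = as.integer(answers_per_question),
                 passages_per_question = as.integer(passages_per_question),
                 n_distractors = as.integer(n_distractors),
                 distractor_vocab = as.integer(distractor_vocab),
                 synonym_prob = synonym_prob, hard_mode = isTRUE(hard_mode),
                 answer_words = as.integer(answer_words),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sentence builder that tracks the character offsets of planted strings.
# Sentences are joined by a single space; offsets are 1-based into the
# finished abstract.
new_sentence_tracker <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(); env$len <- 0L
  env$planted <- data.frame(start = integer(), end = integer(),
                            group = integer(), text = character())
  env
}

track_sentence <- function(env, prefix, planted = NULL, groups = NULL,
                           seps = NULL, suffix = ".") {
  # sentence = prefix + planted[1] + seps[1] + planted[2] + ... + suffix
  base <- env$len + (if (length(env$parts) > 0L) 1L else 0L)  # joining space
  sent <- prefix
  if (!is.null(planted)) for (i in seq_along(planted)) {
    s <- base + nchar(sent) + 1L
    sent <- paste0(sent, planted[i])
    env$planted <- rbind(env$planted, data.frame(
      start = s, end = base + nchar(sent), group = groups[i],
      text = planted[i]))
    if (i < length(planted)) sent <- paste0(sent, seps[i])
  }
  sent <- paste0(sent, suffix)
  env$parts <- c(env$parts, sent)
  env$len <- base + nchar(sent)
  invisible(env)
}

finish_tracker <- function(env) {
  list(text = paste(env$parts, collapse = " "), planted = env$planted)
}

#' Generate a synthetic corpus with planted answers
#'
#' Each question asks which entities of a template category are associated
#' with a pseudo-topic; its `k` gold answers are multi-word pseudo-entity
#' phrases embedded verbatim in a carrier sentence of every linked passage,
#' surrounded by a lead sentence and distractor sentences mentioning
#' unrelated entities. With probability `synonym_prob` an answer group
#' carries an abbreviation variant, planted in its own sentence. All
#' planting positions are returned as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_corpus`: `corpus` (a `qa_corpus` that
#'   round-trips through [write_bioasq()]/[read_bioasq()]), `truth` (data
#'   frame `question_id`, `passage_id`, `group`, `start`, `end`, `text`,
#'   with offsets into the full passage text) and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  distractors <- character(spec$distractor_vocab)
  for (i in seq_len(spec$distractor_vocab)) {
    repeat {
      d <- syn_entity(2L)
      if (!d %in% distractors) break
    }
    distractors[i] <- d
  }

  questions <- list(); passages <- list()
  truth <- data.frame(question_id = character(), passage_id = character(),
                      group = integer(), start = integer(), end = integer(),
                      text = character())
  for (qi in seq_len(spec$n_questions)) {
    qid <- sprintf("synq%04d", qi)
    topic <- { w <- syn_word(); paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w))) }
    category <- sample(SYN_CATEGORIES, 1L)
    k <- if (length(spec$answers_per_question) == 1L) spec$answers_per_question
         else sample(spec$answers_per_question, 1L)
    answers <- character(0)
    for (a in seq_len(k)) {
      tries <- 0L
      repeat {
        cand <- syn_entity(sample(spec$answer_words, 1L))
        tries <- tries + 1L
        clash <- any(vapply(c(answers, distractors), function(x)
          grepl(cand, x, fixed = TRUE) || grepl(x, cand, fixed = TRUE), TRUE))
        if (!clash) break
        if (tries > 100L) stop("vocabulary too small to guarantee distinct answers")
      }
      answers <- c(answers, cand)
    }
    groups <- lapply(answers, identity)
    has_syn <- stats::runif(k) < spec$synonym_prob
    for (a in which(has_syn)) {
      words <- strsplit(answers[a], " ", fixed = TRUE)[[1]]
      abbr <- toupper(paste0(substr(words, 1, 1), collapse = ""))
      abbr <- paste0(abbr, qi %% 10, a)       # keep abbreviations distinct
      groups[[a]] <- c(groups[[a]], abbr)
    }
    refs <- character(spec$passages_per_question)
    for (pj in seq_len(spec$passages_per_question)) {
      pid <- sprintf("%s_p%d", qid, pj)
      refs[pj] <- pid
      title <- sprintf("A study of %s.", topic)
      tr <- new_sentence_tracker()
      track_sentence(tr, sprintf("Recent work has examined %s in several models", topic),
                     suffix = ".")
      seps <- if (k > 1L) c(rep(", ", max(k - 2L, 0L)), " and ") else NULL
      track_sentence(tr, sprintf("The %s associated with %s are ", category, topic),
                     planted = answers, groups = seq_len(k), seps = seps)
      for (a in which(has_syn))
        track_sentence(tr, "The term ", planted = groups[[a]][2L],
                       groups = a, suffix = " is used interchangeably.")
      dset <- sample(distractors, spec$n_distractors)
      for (d in dset) {
        if (spec$hard_mode && stats::runif(1) < 0.5) {
          emb <- sample(k, 1L)
          track_sentence(tr, "Earlier reports described ",
                         planted = answers[emb], groups = emb,
                         suffix = sprintf(" %s in unrelated settings.", syn_word()))
        } else {
          track_sentence(tr, sprintf("Earlier reports described %s in unrelated settings", d),
                         suffix = ".")
        }
      }
      fin <- finish_tracker(tr)
      passages[[length(passages) + 1L]] <- passage_record(pid, title, fin$text)
      if (nrow(fin$planted) > 0L) {
        off <- nchar(title) + 1L              # title + joining space
        truth <- rbind(truth, data.frame(
          question_id = qid, passage_id = pid, group = fin$planted$group,
          start = fin$planted$start + off, end = fin$planted$end + off,
          text = fin$planted$text))
      }
    }
    body <- sprintf("Which %s are associated with %s?", category, topic)
    questions[[length(questions) + 1L]] <-
      question_record(qid, body, "list", groups, refs)
  }
  structure(list(corpus = qa_corpus(questions, passages), truth = truth,
                 spec = spec),
            class = "synthetic_corpus")
}

#' Verify the planting of a synthetic corpus
#'
#' Checks that every emitted truth span slices to its answer string, and
#' that the empirical answers-per-question distribution matches the spec:
#' exactly for a point mass, within 3 standard errors per support value
#' otherwise.
#'
#' @param synthetic A `synthetic_corpus` from [generate_synthetic()].
#' @return A `plant_check` report: `ok` flag, `span_failures` (question ids
#'   with mismatched slices) and `distribution_failures`.
#' @export
plant_check <- function(synthetic) {
  stopifnot(inherits(synthetic, "synthetic_corpus"))
  corpus <- synthetic$corpus; truth <- synthetic$truth; spec <- synthetic$spec
  span_fail <- character()
  for (i in seq_len(nrow(truth))) {
    p <- corpus$passages[[truth$passage_id[i]]]
    if (is.null(p) ||
        substr(p$text, truth$start[i], truth$end[i]) != truth$text[i])
      span_fail <- c(span_fail, truth$question_id[i])
  }
  counts <- vapply(corpus$questions, function(q) length(q$gold_answers), 0L)
  dist_fail <- character()
  support <- spec$answers_per_question
  if (length(support) == 1L) {
    bad <- counts != support
    if (any(bad))
      dist_fail <- vapply(corpus$questions[bad], `[[`, "", "question_id")
  } else {
    n <- length(counts); p0 <- 1 / length(support)
    se <- sqrt(p0 * (1 - p0) / n)
    for (v in support) {
      freq <- mean(counts == v)
      if (abs(freq - p0) > 3 * se)
        dist_fail <- c(dist_fail, sprintf("count=%d freq=%.3f", v, freq))
    }
    if (any(!counts %in% support)) dist_fail <- c(dist_fail, "values outside support")
  }
  structure(list(ok = length(span_fail) == 0L && length(dist_fail) == 0L,
                 span_failures = unique(span_fail),
                 distribution_failures = dist_fail),
            class = "plant_check")
}

#' @export
print.plant_check <- function(x, ...) {
  cat("<plant_check> ", if (x$ok) "OK" else "FAILED", "\n", sep = "")
  if (length(x$span_failures) > 0L)
    cat("  span failures: ", paste(x$span_failures, collapse = ", "), "\n")
  if (length(x$distribution_failures) > 0L)
    cat("  distribution failures: ",
        paste(x$distribution_failures, collapse = "; "), "\n")
  invisible(x)
}
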