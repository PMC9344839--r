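#' @keywords internal
"_PACKAGE"

# ---- domain types -----------------------------------------------------------

#' Construct a question record
#'
#' A question record carries the question text, its type, the gold answers as
#' synonym groups, and the identifiers of the passages linked to it. Gold
#' answers are an ordered list of character vectors: each vector is one
#' synonym group, i.e. the surface variants (synonyms, abbreviations) accepted
#' as the same answer entity. Factoid questions carry exactly one group,
#' list questions one or more.
#'
#' @param question_id Opaque identifier string.
#' @param body Question text; must be non-empty after trimming.
#' @param qtype One of `"factoid"`, `"list"`, `"yesno"`, `"summary"`. Only the
#'   first two are supported for tagging; the others are parsed but flagged.
#' @param gold_answers List of non-empty character vectors (synonym groups).
#'   Ignored (may be empty) for yesno/summary questions.
#' @param passage_refs Character vector of passage identifiers.
#' @return An object of class `qa_question`.
#' @export
question_record <- function(question_id, body, qtype,
                            gold_answers = list(), passage_refs = character()) {
  qtype <- match.arg(qtype, c("factoid", "list", "yesno", "summary"))
  body <- as.character(body)
  if (length(body) != 1L || !nzchar(trimws(body)))
    stop("question body must be a non-empty string (question ", question_id, ")")
  if (qtype %in% c("factoid", "list")) {
    if (length(gold_answers) == 0L)
      stop("question ", question_id, " (", qtype, ") has no gold answers")
    if (qtype == "factoid" && length(gold_answers) != 1L)
      stop("factoid question ", question_id, " must have exactly one synonym group")
    for (g in gold_answers) {
      g <- as.character(g)
      if (length(g) == 0L || any(!nzchar(trimws(g))))
        stop("question ", question_id, ": empty synonym group or empty variant")
    }
  }
  structure(list(question_id = as.character(question_id),
                 body = body, qtype = qtype,
                 gold_answers = lapply(gold_answers, as.character),
                 passage_refs = as.character(passage_refs)),
            class = "qa_question")
}

#' Construct a passage record
#'
#' A passage is a pair of title and abstract; the searchable passage text is
#' their deterministic concatenation via [build_passage_text()].
#'
#' @param passage_id Opaque identifier string.
#' @param title,abstract Passage components; at least one must be non-empty.
#' @return An object of class `qa_passage` with a derived `text` field.
#' @export
passage_record <- function(passage_id, title = "", abstract = "") {
  structure(list(passage_id = as.character(passage_id),
                 title = as.character(title), abstract = as.character(abstract),
                 text = build_passage_text(title, abstract)),
            class = "qa_passage")
}

#' Join title and abstract into the passage text
#'
#' The join rule is `title`, a single space, `abstract`; a character of the
#' abstract at (1-based) position `k` lands at position
#' `nchar(title) + 1 + k` of the passage text. Degenerate cases (one side
#' empty) return the other side unchanged.
#'
#' @param title,abstract Character scalars; not both empty.
#' @return The concatenated passage string.
#' @export
build_passage_text <- function(title, abstract) {
  title <- as.character(title); abstract <- as.character(abstract)
  if (length(title) != 1L || length(abstract) != 1L)
    stop("title and abstract must be character scalars")
  if (!nzchar(title) && !nzchar(abstract))
    stop("both title and abstract are empty")
  if (!nzchar(title)) return(abstract)
  if (!nzchar(abstract)) return(title)
  paste(title, abstract, sep = " ")
}

#' Assemble a corpus object
#'
#' @param questions List of [question_record()] objects.
#' @param passages List of [passage_record()] objects.
#' @return An object of class `qa_corpus`, with passages indexed by id.
#' @export
qa_corpus <- function(questions, passages) {
  stopifnot(all(vapply(questions, inherits, TRUE, "qa_question")),
            all(vapply(passages, inherits, TRUE, "qa_passage")))
  names(passages) <- vapply(passages, `[[`, "", "passage_id")
  if (anyDuplicated(names(passages)))
    stop("duplicate passage identifiers")
  structure(list(questions = questions, passages = passages),
            class = "qa_corpus")
}

#' @export
print.qa_corpus <- function(x, ...) {
  types <- table(vapply(x$questions, `[[`, "", "qtype"))
  cat("<qa_corpus> ", length(x$questions), " questions (",
      paste(names(types), unclass(types), sep = ":", collapse = ", "),
      "), ", length(x$passages), " passages\n", sep = "")
  invisible(x)
}

# ---- BioASQ dialect ---------------------------------------------------------

#' Read a corpus in the BioASQ task-b JSON dialect
#'
#' Expects a top-level `"questions"` array; each entry has `"body"`,
#' `"type"`, and for factoid/list questions an `"exact_answer"`: a flat
#' string array (one synonym group) for factoid, an array of string arrays
#' (one group per inner array) for list. Passage text must be inline: either
#' a `"passages"` array of `{id, title, abstract}` objects (the dialect used
#' by [write_bioasq()] and the synthetic generator; URL retrieval is out of
#' scope), or BioASQ `"snippets"` whose `"text"` becomes the abstract of an
#' auto-identified passage. Yes/no and summary questions are parsed but
#' carry no answers and are skipped by [build_samples()].
#'
#' @param path Path to a JSON file.
#' @return A `qa_corpus`.
#' @export
read_bioasq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$questions)) stop("not a BioASQ dialect file: no 'questions' array")
  questions <- list(); passages <- list()
  for (i in seq_along(doc$questions)) {
    q <- doc$questions[[i]]
    if (is.null(q$body) || is.null(q$type))
      stop("question ", i, ": missing 'body' or 'type'")
    qtype <- as.character(q$type)
    qid <- if (!is.null(q$id)) as.character(q$id) else sprintf("q%04d", i)
    groups <- list()
    if (qtype %in% c("factoid", "list")) {
      if (is.null(q$exact_answer))
        stop("question ", i, " (", qid, "): ", qtype,
             " question without 'exact_answer'")
      ea <- q$exact_answer
      if (qtype == "factoid") {
        # flat string array -> one group; tolerate the single-nested form
        if (length(ea) == 1L && is.list(ea[[1]])) ea <- ea[[1]]
        groups <- list(vapply(ea, as.character, ""))
      } else {
        groups <- lapply(ea, function(g) vapply(as.list(g), as.character, ""))
      }
    }
    refs <- character()
    if (!is.null(q$passages)) {
      for (p in q$passages) {
        pid <- as.character(p$id)
        refs <- c(refs, pid)
        if (is.null(passages[[pid]]))
          passages[[pid]] <- passage_record(pid,
                                            title = if (is.null(p$title)) "" else p$title,
                                            abstract = if (is.null(p$abstract)) "" else p$abstract)
      }
    } else if (!is.null(q$snippets)) {
      for (k in seq_along(q$snippets)) {
        pid <- sprintf("%s_s%02d", qid, k)
        refs <- c(refs, pid)
        passages[[pid]] <- passage_record(pid, title = "",
                                          abstract = q$snippets[[k]]$text)
      }
    }
    questions[[length(questions) + 1L]] <-
      question_record(qid, q$body, qtype, groups, refs)
  }
  qa_corpus(questions, unname(passages))
}

#' Write a corpus in the BioASQ task-b JSON dialect
#'
#' Inverse of [read_bioasq()] for supported question types: factoid
#' `exact_answer` is a flat string array, list `exact_answer` an array of
#' arrays; passages are emitted inline per question.
#'
#' @param corpus A `qa_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioasq <- function(corpus, path) {
  stopifnot(inherits(corpus, "qa_corpus"))
  qs <- lapply(corpus$questions, function(q) {
    entry <- list(id = q$question_id, body = q$body, type = q$qtype)
    if (q$qtype == "factoid") {
      entry$exact_answer <- as.list(q$gold_answers[[1]])
    } else if (q$qtype == "list") {
      entry$exact_answer <- lapply(q$gold_answers, as.list)
    }
    entry$passages <- lapply(q$passage_refs, function(pid) {
      p <- corpus$passages[[pid]]
      list(id = p$passage_id, title = p$title, abstract = p$abstract)
    })
    entry
  })
  jsonlite::write_json(list(questions = qs), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a SQuAD v1 JSON file as factoid records
#'
#' Each question/answer set maps to one factoid question whose single
#' synonym group is the distinct annotated answer texts; each paragraph
#' context becomes one passage (title empty, so passage text equals the
#' context and annotated character offsets stay valid). Used for the
#' transfer pre-training stage.
#'
#' @param path Path to a SQuAD v1 JSON file.
#' @return A `qa_corpus` of factoid questions.
#' @export
read_squad <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$data)) stop("not a SQuAD file: no 'data' array")
  questions <- list(); passages <- list(); pidx <- 0L
  for (art in doc$data) {
    for (par in art$paragraphs) {
      pidx <- pidx + 1L
      pid <- sprintf("squad_p%05d", pidx)
      passages[[pid]] <- passage_record(pid, title = "", abstract = par$context)
      for (qa in par$qas) {
        answers <- unique(vapply(qa$answers, function(a) as.character(a$text), ""))
        answers <- answers[nzchar(trimws(answers))]
        if (length(answers) == 0L) next
        qid <- if (!is.null(qa$id)) as.character(qa$id)
               else sprintf("squad_q%05d", length(questions) + 1L)
        questions[[length(questions) + 1L]] <-
          question_record(qid, qa$question, "factoid", list(answers), pid)
      }
    }
  }
  qa_corpus(questions, unname(passages))
}

# ---- sample construction ----------------------------------------------------

#' Build training/evaluation samples from a corpus
#'
#' A sample is one question-passage-answer triplet. Passages in which no gold
#' answer can be located are excluded. For a question with `i` matchable
#' passages and `j` matched answers (synonym groups) per passage, the
#' `single_span` configuration yields one sample per (passage, matched group)
#' pair -- `i*j` when all groups match everywhere -- while `seq_tag` yields
#' one multi-span sample per matchable passage, `i` in total. Yes/no and
#' summary questions contribute no samples.
#'
#' @param corpus A `qa_corpus`.
#' @param configuration `"seq_tag"` (default) or `"single_span"`.
#' @param match_mode Passed to [find_answer_spans()]: `"uncased"` (default)
#'   or `"cased"`.
#' @param expand_variants For `single_span` only: if `TRUE`, one sample per
#'   (passage, matched variant) instead of per (passage, group). Default
#'   `FALSE`, reproducing the `i*j` count with `j` = number of groups.
#' @return A list of `qa_sample` objects, each holding `question_id`,
#'   `passage_id` and a data frame of matched spans (`start`, `end`,
#'   `group`; 1-based inclusive character coordinates).
#' @export
build_samples <- function(corpus, configuration = c("seq_tag", "single_span"),
                          match_mode = c("uncased", "cased"),
                          expand_variants = FALSE) {
  stopifnot(inherits(corpus, "qa_corpus"))
  configuration <- match.arg(configuration)
  match_mode <- match.arg(match_mode)
  samples <- list()
  for (q in corpus$questions) {
    if (!q$qtype %in% c("factoid", "list")) next
    for (pid in q$passage_refs) {
      p <- corpus$passages[[pid]]
      if (is.null(p))
        stop("question ", q$question_id, " references unknown passage '", pid, "'")
      spans <- find_answer_spans(p$text, q$gold_answers, match_mode)
      if (nrow(spans) == 0L) next               # the matching filter
      if (configuration == "seq_tag") {
        samples[[length(samples) + 1L]] <- structure(
          list(question_id = q$question_id, passage_id = pid, spans = spans),
          class = "qa_sample")
      } else {
        key <- if (expand_variants) seq_len(nrow(spans)) else spans$group
        for (k in sort(unique(key))) {
          first <- which(key == k)[1L]          # first (leftmost) match
          samples[[length(samples) + 1L]] <- structure(
            list(question_id = q$question_id, passage_id = pid,
                 spans = spans[first, , drop = FALSE]),
            class = "qa_sample")
        }
      }
    }
  }
  samples
}

#' Serialize samples to JSON
#'
#' Writes the output of [build_samples()] as a JSON array of
#' `{question_id, passage_id, spans: [{start, end, group}]}` objects, in
#' deterministic order. Used by the `convert` command-line entry point.
#'
#' @param samples List of `qa_sample` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  out <- lapply(samples, function(s)
    list(question_id = s$question_id, passage_id = s$passage_id,
         spans = lapply(seq_len(nrow(s$spans)), function(i)
           list(start = s$spans$start[i], end = s$spans$end[i],
                group = s$spans$group[i]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
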