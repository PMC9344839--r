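# Answer-span location, input-sequence construction and BIO labelling.
# Character coordinates throughout are 1-based inclusive (substr convention).

#' Locate gold answers in a passage
#'
#' Finds every occurrence of every variant of every synonym group in the
#' passage text, then resolves overlaps longest-leftmost: candidates are
#' considered in order of start position (earlier first), ties broken by
#' length (longer first), and a candidate is kept only if it does not
#' overlap an already-kept span. Matching is exact substring search,
#' word-boundary-agnostic. In `"uncased"` mode both sides are lower-cased
#' before the search but spans are reported in the original coordinates.
#'
#' @param passage_text Non-empty passage string.
#' @param synonym_groups List of character vectors (one vector per group).
#' @param match_mode `"uncased"` (default) or `"cased"`.
#' @return A data frame with columns `start`, `end` (1-based inclusive) and
#'   `group` (index into `synonym_groups`), ordered by `start`. Zero rows
#'   when nothing matches.
#' @export
find_answer_spans <- function(passage_text, synonym_groups,
                              match_mode = c("uncased", "cased")) {
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(passage_text), length(passage_text) == 1L,
            nzchar(passage_text))
  hay <- if (match_mode == "uncased") tolower(passage_text) else passage_text
  starts <- integer(); ends <- integer(); groups <- integer()
  for (gi in seq_along(synonym_groups)) {
    for (v in synonym_groups[[gi]]) {
      if (!nzchar(v)) next
      needle <- if (match_mode == "uncased") tolower(v) else v
      hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      starts <- c(starts, as.integer(hits))
      ends <- c(ends, as.integer(hits) + nchar(needle) - 1L)
      groups <- c(groups, rep.int(gi, length(hits)))
    }
  }
  if (length(starts) == 0L)
    return(data.frame(start = integer(), end = integer(), group = integer()))
  ord <- order(starts, -(ends - starts), groups)
  starts <- starts[ord]; ends <- ends[ord]; groups <- groups[ord]
  keep <- logical(length(starts)); last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ends[i]
    }
  }
  data.frame(start = starts[keep], end = ends[keep], group = groups[keep])
}

# ---- tokenizer --------------------------------------------------------------

#' A simple sub-word tokenizer
#'
#' Splits text into alphanumeric runs and single punctuation characters,
#' then breaks runs longer than `max_piece` characters into fixed-width
#' pieces, flagging every non-initial piece as a continuation (the sub-word
#' mechanism that the supervision-masking and detokenization paths must
#' handle; it stands in for WordPiece, whose vocabularies are external).
#' Character offsets into the source string are kept for every piece, so
#' decoding recovers original substrings exactly.
#'
#' @param max_piece Maximum piece length in characters (default 6).
#' @param lowercase Lower-case token strings (offsets still index the
#'   original text). Matches an uncased encoder; default `TRUE`.
#' @return An object of class `qa_tokenizer`: a list with elements
#'   `tokenize(text)` (returns a data frame `token`, `start`, `end`,
#'   `continuation`), `lowercase` and `max_piece`.
#' @export
word_tokenizer <- function(max_piece = 6L, lowercase = TRUE) {
  stopifnot(max_piece >= 1L)
  tokenize <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    empty <- data.frame(token = character(), start = integer(),
                        end = integer(), continuation = logical())
    if (!nzchar(text)) return(empty)
    m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1]]
    if (m[1] == -1L) return(empty)
    ws <- as.integer(m); wl <- attr(m, "match.length")
    tok <- character(); st <- integer(); en <- integer(); cont <- logical()
    for (i in seq_along(ws)) {
      pieces <- seq.int(0L, wl[i] - 1L, by = max_piece)
      for (k in seq_along(pieces)) {
        s <- ws[i] + pieces[k]
        e <- min(ws[i] + wl[i] - 1L, s + max_piece - 1L)
        tok <- c(tok, substr(text, s, e))
        st <- c(st, s); en <- c(en, e); cont <- c(cont, k > 1L)
      }
    }
    if (lowercase) tok <- tolower(tok)
    data.frame(token = tok, start = st, end = en, continuation = cont)
  }
  structure(list(tokenize = tokenize, lowercase = lowercase,
                 max_piece = as.integer(max_piece)),
            class = "qa_tokenizer")
}

#' Build the model input sequence for a question-passage pair
#'
#' Lays out `[CLS] question [SEP] passage [SEP]`, mirroring the BERT-style
#' input convention. If the sequence would exceed `max_len` tokens the
#' passage is truncated from the tail; question tokens are never truncated.
#'
#' @param question_text,passage_text Source strings.
#' @param tokenizer A [word_tokenizer()] (or any object with the same
#'   `tokenize` contract).
#' @param max_len Maximum sequence length in tokens (default 512).
#' @return An object of class `tokenized_input`: parallel vectors `tokens`,
#'   `origin` (`"special"`, `"question"`, `"passage"`), `start`, `end`
#'   (`NA` for special tokens; question/passage offsets index their own
#'   source string) and `continuation`, plus the two source strings.
#' @export
tokenize_and_pack <- function(question_text, passage_text, tokenizer,
                              max_len = 512L) {
  qt <- tokenizer$tokenize(question_text)
  pt <- tokenizer$tokenize(passage_text)
  budget <- max_len - nrow(qt) - 3L           # [CLS], 2x [SEP]
  if (budget < 0L || nrow(qt) > max_len - 3L)
    stop("question alone exceeds max_len - 3 tokens (", nrow(qt), " > ",
         max_len - 3L, ")")
  if (nrow(pt) == 0L || budget == 0L)
    stop("no room for any passage token (passage empty or question too long)")
  pt <- utils::head(pt, budget)
  tokens <- c("[CLS]", qt$token, "[SEP]", pt$token, "[SEP]")
  origin <- c("special", rep("question", nrow(qt)), "special",
              rep("passage", nrow(pt)), "special")
  start <- c(NA_integer_, qt$start, NA_integer_, pt$start, NA_integer_)
  end <- c(NA_integer_, qt$end, NA_integer_, pt$end, NA_integer_)
  continuation <- c(FALSE, qt$continuation, FALSE, pt$continuation, FALSE)
  structure(list(tokens = tokens, origin = origin, start = start, end = end,
                 continuation = continuation,
                 question_text = question_text, passage_text = passage_text),
            class = "tokenized_input")
}

#' @export
print.tokenized_input <- function(x, ...) {
  cat("<tokenized_input> ", length(x$tokens), " tokens (",
      sum(x$origin == "question"), " question, ",
      sum(x$origin == "passage"), " passage)\n", sep = "")
  invisible(x)
}

# Positions that carry supervision and are decoded: word-initial passage pieces.
supervised_positions <- function(tokenized) {
  which(tokenized$origin == "passage" & !tokenized$continuation)
}

#' Assign BIO labels with supervision masking
#'
#' For each answer span, the first supervised passage token overlapping it
#' (character-range overlap) is labelled `B`, subsequent overlapping
#' supervised tokens `I`; supervised passage tokens outside all spans get
#' `O`. Special tokens, question tokens and sub-word continuation pieces are
#' labelled `IGNORE` and excluded from the loss, so the model is never
#' penalized there. Adjacent spans each open their own `B`. Spans that fell
#' entirely beyond the truncated passage window are dropped with a warning.
#'
#' @param tokenized A `tokenized_input`.
#' @param spans Data frame with `start`, `end` columns (1-based inclusive,
#'   passage coordinates), non-overlapping.
#' @return Character vector of labels over `{B, I, O, IGNORE}`, aligned to
#'   `tokenized$tokens`.
#' @export
assign_bio_labels <- function(tokenized, spans) {
  stopifnot(inherits(tokenized, "tokenized_input"))
  labels <- rep("IGNORE", length(tokenized$tokens))
  sup <- supervised_positions(tokenized)
  labels[sup] <- "O"
  if (is.null(spans) || nrow(spans) == 0L) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (nrow(spans) > 1L && any(spans$start[-1] <= spans$end[-nrow(spans)]))
    stop("overlapping input spans; resolve overlaps before labelling")
  for (i in seq_len(nrow(spans))) {
    hit <- sup[!is.na(tokenized$start[sup]) &
               tokenized$start[sup] <= spans$end[i] &
               tokenized$end[sup] >= spans$start[i]]
    if (length(hit) == 0L) {
      warning("span [", spans$start[i], ",", spans$end[i],
              "] lies beyond the truncated passage window; dropped")
      next
    }
    labels[hit[1]] <- "B"
    if (length(hit) > 1L) labels[hit[-1]] <- "I"
  }
  labels
}
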