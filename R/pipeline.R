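# High-level glue: corpus -> labelled training samples -> fitted tagger.

#' Build BIO-labelled training samples from a corpus
#'
#' Runs [build_samples()] in the requested configuration, then tokenizes
#' each question-passage pair and assigns masked BIO labels to the matched
#' spans. Spans lost to truncation at `max_len` are dropped with a warning
#' (a documented limitation of tail truncation).
#'
#' @param corpus A `qa_corpus`.
#' @param tokenizer A [word_tokenizer()].
#' @param configuration `"seq_tag"` (default) or `"single_span"`.
#' @param match_mode `"uncased"` (default) or `"cased"`.
#' @param max_len Maximum input length in tokens (default 512).
#' @return List of samples: each a list with `tok`, `labels`,
#'   `question_id`, `passage_id`.
#' @export
prepare_samples <- function(corpus, tokenizer,
                            configuration = c("seq_tag", "single_span"),
                            match_mode = c("uncased", "cased"),
                            max_len = 512L) {
  configuration <- match.arg(configuration)
  match_mode <- match.arg(match_mode)
  raw <- build_samples(corpus, configuration, match_mode)
  lapply(raw, function(s) {
    q <- Find(function(x) x$question_id == s$question_id, corpus$questions)
    p <- corpus$passages[[s$passage_id]]
    tok <- tokenize_and_pack(q$body, p$text, tokenizer, max_len = max_len)
    list(tok = tok, labels = assign_bio_labels(tok, s$spans),
         question_id = s$question_id, passage_id = s$passage_id)
  })
}

#' Fit a span tagger on a corpus
#'
#' Convenience wrapper: [prepare_samples()] then [train_tagger()]. For the
#' two-stage transfer schedule, fit on the transfer corpus first (higher
#' learning rate), then pass the result as `init_model` with the target
#' corpus.
#'
#' @param corpus A `qa_corpus`.
#' @param config A [train_config()].
#' @param tokenizer A [word_tokenizer()]; defaults to
#'   `word_tokenizer()`.
#' @param init_model Optional warm-start model (transfer stage).
#' @return A fitted `span_tagger` with the tokenizer attached.
#' @export
fit_span_tagger <- function(corpus, config, tokenizer = word_tokenizer(),
                            init_model = NULL) {
  samples <- prepare_samples(corpus, tokenizer, "seq_tag",
                             max_len = config$max_len)
  if (length(samples) == 0L) stop("corpus yields no trainable samples")
  model <- train_tagger(samples, config, init_model = init_model)
  model$tokenizer <- tokenizer
  model
}

#' Command-line corpus conversion
#'
#' Implements `convert --input FILE --format bioasq|squad --config
#' single_span|seq_tag --output FILE`: reads a corpus, builds samples under
#' the chosen configuration and writes them as JSON. An executable wrapper
#' ships in `inst/cli/convert.R`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the number of samples written.
#' @export
run_convert_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the convert CLI requires the 'optparse' package")
  parser <- optparse::OptionParser(
    prog = "convert",
    option_list = list(
      optparse::make_option("--input", type = "character"),
      optparse::make_option("--format", type = "character", default = "bioasq"),
      optparse::make_option("--config", type = "character", default = "seq_tag"),
      optparse::make_option("--output", type = "character")))
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$input) || is.null(opt$output))
    stop("--input and --output are required")
  corpus <- switch(match.arg(opt$format, c("bioasq", "squad")),
                   bioasq = read_bioasq(opt$input),
                   squad = read_squad(opt$input))
  samples <- build_samples(corpus, match.arg(opt$config,
                                             c("seq_tag", "single_span")))
  write_samples(samples, opt$output)
  message(length(samples), " samples written to ", opt$output)
  invisible(length(samples))
}
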