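# Small fixtures built in code.

fixture_corpus <- function() {
  q1 <- question_record("q1", "Which drugs inhibit COX?", "list",
                        list(c("aspirin"), c("ibuprofen", "Advil")),
                        c("p1", "p2"))
  q2 <- question_record("q2", "What gene causes X?", "factoid",
                        list(c("BRCA1", "breast cancer 1")), "p1")
  q3 <- question_record("q3", "Is aspirin an NSAID?", "yesno")
  p1 <- passage_record("p1", "COX inhibitors.",
                       "Aspirin and ibuprofen block COX. BRCA1 is unrelated.")
  p2 <- passage_record("p2", "Analgesics.",
                       "Advil is a brand of ibuprofen; aspirin differs.")
  qa_corpus(list(q1, q2, q3), list(p1, p2))
}

# tokenized input over n one-character passage words ("a b c ...")
toy_tokenized <- function(n) {
  passage <- paste(letters[seq_len(n)], collapse = " ")
  tokenize_and_pack("q?", passage, word_tokenizer())
}

# split a held-out tail off a generated corpus
split_corpus <- function(corpus, n_train) {
  take <- function(qs) {
    refs <- unlist(lapply(qs, `[[`, "passage_refs"))
    qa_corpus(qs, unname(corpus$passages[refs]))
  }
  list(train = take(corpus$questions[seq_len(n_train)]),
       test = take(corpus$questions[(n_train + 1L):length(corpus$questions)]))
}
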