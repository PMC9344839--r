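test_that("find_answer_spans locates literal occurrences", {
  sp <- find_answer_spans("aspirin and ibuprofen",
                          list("aspirin", "ibuprofen"), "uncased")
  expect_equal(sp$start, c(1, 13))
  expect_equal(sp$end, c(7, 21))
  expect_equal(sp$group, c(1, 2))
  expect_equal(nrow(find_answer_spans("X", list("aspirin"))), 0)
})

test_that("overlap resolution is longest-leftmost", {
  sp <- find_answer_spans("heat shock protein response",
                          list(c("heat shock protein", "heat")))
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$start, sp$end), c(1, 18))
  # brute-force oracle: enumerate all occurrences of all variants, then
  # greedily keep by (start asc, length desc)
  text <- "abc ab abc ab"
  groups <- list("abc", "ab")
  occ <- do.call(rbind, lapply(seq_along(groups), function(g) {
    do.call(rbind, lapply(groups[[g]], function(v) {
      hits <- gregexpr(v, text, fixed = TRUE)[[1]]
      if (hits[1] == -1) return(NULL)
      data.frame(start = as.integer(hits),
                 end = as.integer(hits) + nchar(v) - 1L, group = g)
    }))
  }))
  occ <- occ[order(occ$start, -(occ$end - occ$start)), ]
  kept <- occ[0, ]; last_end <- 0
  for (r in seq_len(nrow(occ)))
    if (occ$start[r] > last_end) { kept <- rbind(kept, occ[r, ]); last_end <- occ$end[r] }
  got <- find_answer_spans(text, groups)
  expect_equal(got$start, kept$start)
  expect_equal(got$end, kept$end)
})

test_that("uncased matching reports original coordinates", {
  sp <- find_answer_spans("Aspirin works", list("aspirin"), "uncased")
  expect_equal(c(sp$start, sp$end), c(1, 7))
  expect_equal(nrow(find_answer_spans("Aspirin works", list("aspirin"),
                                      "cased")), 0)
})

test_that("tokenizer splits long words into offset-true pieces", {
  tk <- word_tokenizer(max_piece = 4)
  d <- tk$tokenize("p53-dependent")
  expect_equal(d$token, c("p53", "-", "depe", "nden", "t"))
  expect_equal(d$continuation, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # offsets slice back to the original text
  expect_equal(substr("p53-dependent", d$start[3], d$end[5]), "dependent")
})

test_that("tokenize_and_pack lays out [CLS] q [SEP] p [SEP] and truncates", {
  tk <- word_tokenizer()
  tok <- tokenize_and_pack("Which drug?", "Aspirin works.", tk)
  expect_equal(tok$tokens[1], "[CLS]")
  expect_equal(sum(tok$tokens == "[SEP]"), 2)
  seps <- which(tok$origin == "special")
  qr <- which(tok$origin == "question")
  pr <- which(tok$origin == "passage")
  expect_true(max(qr) < seps[2] && seps[2] < min(pr))
  # tail truncation: passage budget respected, question never cut
  long_p <- paste(rep("word", 600), collapse = " ")
  tok2 <- tokenize_and_pack("Which drug?", long_p, tk, max_len = 32)
  expect_lte(length(tok2$tokens), 32)
  expect_equal(sum(tok2$origin == "question"), length(tk$tokenize("Which drug?")$token))
  # degenerate: question alone fills the window
  long_q <- paste(rep("word", 40), collapse = " ")
  expect_error(tokenize_and_pack(long_q, "p", tk, max_len = 32), "max_len")
})

test_that("offsets reproduce every passage word (round-trip property)", {
  tk <- word_tokenizer(max_piece = 4)
  set.seed(42)
  for (i in 1:50) {
    words <- replicate(sample(3:12, 1),
      paste(sample(letters, sample(1:10, 1), TRUE), collapse = ""))
    text <- paste(words, collapse = " ")
    tok <- tokenize_and_pack("q?", text, tk)
    pr <- tok$origin == "passage"
    rebuilt <- vapply(which(pr), function(k)
      substr(text, tok$start[k], tok$end[k]), "")
    # joining pieces word by word reproduces the original words
    word_id <- cumsum(!tok$continuation[pr])
    expect_equal(unname(tapply(rebuilt, word_id, paste, collapse = "")),
                 words, ignore_attr = TRUE)
  }
})

test_that("assign_bio_labels implements the masking rules", {
  tk <- word_tokenizer()
  passage <- "aspirin naproxen other"
  tok <- tokenize_and_pack("Which drugs?", passage, tk)
  # no spans: supervised passage tokens O, everything else IGNORE
  labs <- assign_bio_labels(tok, NULL)
  sup <- tok$origin == "passage" & !tok$continuation
  expect_true(all(labs[sup] == "O"))
  expect_true(all(labs[!sup] == "IGNORE"))
  # two adjacent one-word answers: B B, not B I
  spans <- data.frame(start = c(1, 9), end = c(7, 16))
  labs <- assign_bio_labels(tok, spans)
  expect_equal(labs[sup], c("B", "B", "O"))
})

test_that("sub-word continuations never carry supervision", {
  tk <- word_tokenizer(max_piece = 3)
  tok <- tokenize_and_pack("q?", "abcdefghi xyz", tk)
  pieces <- which(tok$origin == "passage")[1:3]
  expect_equal(tok$continuation[pieces], c(FALSE, TRUE, TRUE))
  labs <- assign_bio_labels(tok, data.frame(start = 1, end = 9))
  expect_equal(labs[pieces], c("B", "IGNORE", "IGNORE"))
})

test_that("label invariants: B count, question-invariance, span errors", {
  tk <- word_tokenizer()
  passage <- "alpha beta gamma delta"
  spans <- data.frame(start = c(1, 12), end = c(10, 16))
  t1 <- tokenize_and_pack("Which?", passage, tk)
  t2 <- tokenize_and_pack("A completely different question text?", passage, tk)
  l1 <- assign_bio_labels(t1, spans); l2 <- assign_bio_labels(t2, spans)
  expect_equal(sum(l1 == "B"), nrow(spans))
  expect_equal(l1[t1$origin == "passage"], l2[t2$origin == "passage"])
  expect_error(assign_bio_labels(t1, data.frame(start = c(1, 5), end = c(10, 16))),
               "overlapping")
  # span beyond the truncation window is dropped with a warning
  tok3 <- tokenize_and_pack("q?", paste(rep("word", 50), collapse = " "),
                            tk, max_len = 12)
  expect_warning(assign_bio_labels(tok3, data.frame(start = 240, end = 246)),
                 "truncated")
})
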