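# Reference re-implementation of the BIO run rule for a label string over
# supervised one-letter words: returns word indices (start, end) per span,
# with orphan I opening a new span.
bio_runs <- function(labs) {
  runs <- list(); open <- NULL
  for (i in seq_along(labs)) {
    if (labs[i] == "B" || (labs[i] == "I" && is.null(open))) {
      if (!is.null(open)) runs[[length(runs) + 1]] <- open
      open <- c(i, i)
    } else if (labs[i] == "I") {
      open[2] <- i
    } else {
      if (!is.null(open)) runs[[length(runs) + 1]] <- open
      open <- NULL
    }
  }
  if (!is.null(open)) runs[[length(runs) + 1]] <- open
  runs
}

test_that("labels_to_spans matches the run truth table for all short patterns", {
  for (L in 1:3) {
    tok <- toy_tokenized(L)
    sup <- which(tok$origin == "passage" & !tok$continuation)
    grid <- expand.grid(rep(list(c("B", "I", "O")), L), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      labs_sup <- unlist(grid[r, ], use.names = FALSE)
      labels <- rep("IGNORE", length(tok$tokens))
      labels[sup] <- labs_sup
      got <- labels_to_spans(labels, tok)
      want <- bio_runs(labs_sup)
      expect_equal(nrow(got), length(want))
      for (k in seq_along(want)) {
        # one-letter words at positions 1, 3, 5, ...: word i covers 2i-1
        expect_equal(got$start[k], 2 * want[[k]][1] - 1)
        expect_equal(got$end[k], 2 * want[[k]][2] - 1)
      }
    }
  }
})

test_that("span -> labels -> span is the identity on non-overlapping spans", {
  # exhaustively: every label string of length <= 6 decodes to spans whose
  # canonical relabelling decodes to the same spans
  for (L in c(4, 6)) {
    tok <- toy_tokenized(L)
    sup <- which(tok$origin == "passage" & !tok$continuation)
    grid <- expand.grid(rep(list(c("B", "I", "O")), L), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      labels <- rep("IGNORE", length(tok$tokens))
      labels[sup] <- unlist(grid[r, ], use.names = FALSE)
      spans <- labels_to_spans(labels, tok)
      relab <- assign_bio_labels(tok, spans)
      expect_equal(labels_to_spans(relab, tok), spans)
    }
  }
})

test_that("orphan I is repaired to B", {
  tok <- toy_tokenized(4)
  sup <- which(tok$origin == "passage" & !tok$continuation)
  labels <- rep("IGNORE", length(tok$tokens))
  labels[sup] <- c("O", "I", "I", "O")
  got <- labels_to_spans(labels, tok)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(3, 5))
  labels[sup] <- c("B", "I", "O", "B")
  expect_equal(nrow(labels_to_spans(labels, tok)), 2)
  labels[sup] <- c("O", "O", "O", "O")
  expect_equal(nrow(labels_to_spans(labels, tok)), 0)
})

test_that("detokenize is exact substring recovery", {
  text <- "Binding of (TNF-α) is p53-dependent here."
  tk <- word_tokenizer(max_piece = 3)
  tok <- tokenize_and_pack("q?", text, tk)
  # spans carry original offsets: sub-words and punctuation come back exact
  sp1 <- find_answer_spans(text, list("p53-dependent"))
  expect_equal(detokenize(sp1, text), "p53-dependent")
  sp2 <- find_answer_spans(text, list("(TNF-α)"))
  expect_equal(detokenize(sp2, text), "(TNF-α)")
  # and the full label round trip reproduces them
  spans <- rbind(sp1[, 1:2], sp2[, 1:2])
  labs <- assign_bio_labels(tok, spans[order(spans$start), ])
  back <- labels_to_spans(labs, tok)
  expect_setequal(vapply(seq_len(nrow(back)), function(i)
    detokenize(back[i, ], text), ""), c("p53-dependent", "(TNF-α)"))
  expect_error(detokenize(data.frame(start = 5, end = 999), text), "range")
})

test_that("score_candidate: softmax rule closed forms", {
  tok <- toy_tokenized(3)
  L <- length(tok$tokens)
  S <- matrix(0, L, 3)
  sup <- which(tok$origin == "passage" & !tok$continuation)
  # uniform scores: every candidate scores 1/3
  expect_equal(score_candidate(data.frame(start = 1, end = 1), S, tok),
               1 / 3, tolerance = 1e-12)
  # single-token span with softmax probability 0.9 for B
  p <- c(0.9, 0.06, 0.04)
  S[sup[2], ] <- log(p)
  expect_equal(score_candidate(data.frame(start = 3, end = 3), S, tok),
               0.9, tolerance = 1e-12)
})

test_that("score_candidate: CRF marginal matches exhaustive enumeration", {
  set.seed(31)
  for (rep_i in 1:5) {
    n <- 5
    tok <- toy_tokenized(n)
    sup <- which(tok$origin == "passage" & !tok$continuation)
    L <- length(tok$tokens)
    inst <- random_crf_instance(L, scale = 1)
    tr <- crf_transitions(inst$trans, inst$start, inst$end)
    span <- data.frame(start = 3, end = 7)    # words 2..4
    got <- score_candidate(span, inst$S, tok, method = "crf", transitions = tr)
    want <- enum_span_marginal(inst$S, inst$trans, inst$start, inst$end,
                               positions = sup[2:4], labels = c("B", "I", "I"))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("aggregation dedupes by normalized text, keeps max score, no cap", {
  cands <- data.frame(
    text = c("Aspirin", "aspirin ", "ibuprofen", paste0("drug", 1:7)),
    score = c(0.4, 0.9, 0.5, seq(0.7, 0.1, length.out = 7)),
    passage_id = "p1")
  pred <- aggregate_candidates("q1", cands)
  expect_equal(nrow(pred$answers), 9)         # 7 distinct + 2 dedup survivors
  a1 <- pred$answers[pred$answers$text %in% c("Aspirin", "aspirin "), ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$score, 0.9)
  expect_equal(pred$answers$score, sort(pred$answers$score, decreasing = TRUE))
  empty <- aggregate_candidates("q2", NULL)
  expect_equal(nrow(empty$answers), 0)
})

test_that("threshold filter reproduces the 1/t bound; native decoder has none", {
  set.seed(37)
  for (t in c(0.2, 0.1)) {
    for (rep_i in 1:20) {
      n <- sample(1:15, 1)
      pred <- aggregate_candidates("q", data.frame(
        text = paste0("c", seq_len(n)), score = runif(n), passage_id = "p"))
      kept <- threshold_filter(pred, t)
      expect_lte(nrow(kept$answers), floor(1 / t))
    }
  }
  # native aggregation never truncates
  many <- aggregate_candidates("q", data.frame(
    text = paste0("c", 1:12), score = runif(12), passage_id = "p"))
  expect_equal(nrow(many$answers), 12)
})
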