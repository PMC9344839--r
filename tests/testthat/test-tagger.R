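test_that("linear head: identity case, permutation, dimension guard", {
  X <- matrix(rnorm(12), 4, 3)
  h0 <- linear_head(matrix(0, 3, 3), numeric(3))
  expect_equal(score_tokens(X, h0), matrix(0, 4, 3))
  h <- linear_head(matrix(rnorm(9), 3, 3), rnorm(3))
  S <- score_tokens(X, h)
  # per-token affine map: permuting identical rows permutes scores
  Xp <- X[c(2, 1, 3, 4), ]
  expect_equal(score_tokens(Xp, h), S[c(2, 1, 3, 4), ])
  expect_error(score_tokens(matrix(0, 2, 5), h), "match")
})

test_that("BiLSTM single-step output equals the hand-unrolled recurrence", {
  set.seed(1)
  D <- 2L; H <- 2L
  dir <- function() list(Wx = matrix(rnorm(D * 4 * H), D, 4 * H),
                         Wh = matrix(rnorm(H * 4 * H), H, 4 * H),
                         b = rnorm(4 * H))
  fwd <- dir(); bwd <- dir()
  W <- matrix(rnorm(2 * H * 3), 2 * H, 3); b <- rnorm(3)
  head <- bilstm_head(fwd, bwd, W, b)
  x <- rnorm(D)
  # hand-computed one-step LSTM (h0 = c0 = 0): z = x Wx + b
  sig <- function(z) 1 / (1 + exp(-z))
  step <- function(par) {
    z <- drop(x %*% par$Wx) + par$b
    i <- sig(z[1:H]); f <- sig(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sig(z[(3 * H + 1):(4 * H)])
    o * tanh(i * g)
  }
  expected <- drop(c(step(fwd), step(bwd)) %*% W) + b
  got <- score_tokens(matrix(x, 1, D), head)
  expect_equal(drop(got), expected, tolerance = 1e-12)
})

test_that("masked_loss: closed form, masking contract, batch reduction", {
  S <- matrix(0, 6, 3)                        # uniform over 3 labels
  labels <- c("IGNORE", "B", "I", "O", "B", "IGNORE")
  expect_equal(masked_loss(S, labels), log(3), tolerance = 1e-12)
  # the mask is stored in-band as the IGNORE label, so "relabeling a masked
  # position" means changing what the model predicted there: scores at
  # IGNORE positions are arbitrary and must not move the loss bit for bit,
  # and the gradient there is exactly zero
  set.seed(7)
  S2 <- matrix(rnorm(18), 6, 3)
  base <- masked_loss(S2, labels)
  for (rep_i in 1:3) {
    S3 <- S2
    S3[c(1, 6), ] <- rnorm(6) * 100
    expect_identical(masked_loss(S3, labels), base)
  }
  g <- listqa:::masked_loss_grad(S2, labels)
  expect_identical(g$dS_sum[c(1, 6), ], matrix(0, 2, 3))
  expect_error(masked_loss(S, rep("IGNORE", 6)), "IGNORE")
  # documented batch reduction: total CE / total supervised count
  Sa <- matrix(rnorm(9), 3, 3); la <- c("B", "IGNORE", "O")
  Sb <- matrix(rnorm(12), 4, 3); lb <- c("I", "O", "O", "B")
  ga <- listqa:::masked_loss_grad(Sa, la); gb <- listqa:::masked_loss_grad(Sb, lb)
  pooled <- (ga$ce_sum + gb$ce_sum) / (ga$n_sup + gb$n_sup)
  # explicit summation oracle
  ce <- function(S, l) {
    tot <- 0
    for (t in seq_along(l)) if (l[t] != "IGNORE") {
      p <- exp(S[t, ]) / sum(exp(S[t, ]))
      tot <- tot + -log(p[match(l[t], c("B", "I", "O"))])
    }
    tot
  }
  expect_equal(pooled, (ce(Sa, la) + ce(Sb, lb)) / 6, tolerance = 1e-12)
})

test_that("CRF log-likelihood: closed form at L = 1 and enumeration at L <= 6", {
  set.seed(11)
  tr <- crf_transitions(matrix(rnorm(9), 3, 3), rnorm(3), rnorm(3))
  s1 <- matrix(rnorm(3), 1, 3)
  ll <- crf_log_likelihood(s1, tr, "I")
  v <- s1[1, ] + tr$start + tr$end
  expect_equal(ll, unname(v[2]) - log(sum(exp(v))), tolerance = 1e-12)
  for (L in 2:6) {
    inst <- random_crf_instance(L)
    tri <- crf_transitions(inst$trans, inst$start, inst$end)
    labels <- sample(c("B", "I", "O"), L, replace = TRUE)
    gold <- crf_log_likelihood(inst$S, tri, labels)
    logZ <- enum_log_partition(inst$S, inst$trans, inst$start, inst$end)
    y <- match(labels, c("B", "I", "O"))
    path <- inst$start[y[1]] + inst$end[y[L]] +
      sum(inst$S[cbind(1:L, y)]) + sum(inst$trans[cbind(y[-L], y[-1])])
    expect_equal(gold, path - logZ, tolerance = 1e-9)
    expect_lte(path, logZ)                    # one summand of the partition
  }
  expect_error(crf_log_likelihood(matrix(c(1, NA, 0), 1, 3), tr, "B"),
               "non-finite")
  expect_error(crf_log_likelihood(s1, tr, "IGNORE"), "labels")
})

test_that("CRF gradients match finite differences", {
  set.seed(13)
  inst <- random_crf_instance(4, scale = 1)
  y <- c(1L, 2L, 3L, 1L)
  tr <- crf_transitions(inst$trans, inst$start, inst$end)
  g <- listqa:::crf_grad(inst$S, tr, y)
  eps <- 1e-6
  for (k in sample(12, 4)) {
    Sp <- inst$S; Sp[k] <- Sp[k] + eps
    Sm <- inst$S; Sm[k] <- Sm[k] - eps
    lab <- c("B", "I", "O")[y]
    num <- (crf_log_likelihood(Sp, tr, lab) -
            crf_log_likelihood(Sm, tr, lab)) / (2 * eps)
    expect_equal(g$dS[k], num, tolerance = 1e-5)
  }
  for (k in sample(9, 3)) {
    Tp <- inst$trans; Tp[k] <- Tp[k] + eps
    Tm <- inst$trans; Tm[k] <- Tm[k] - eps
    lab <- c("B", "I", "O")[y]
    num <- (crf_log_likelihood(inst$S, crf_transitions(Tp, inst$start, inst$end), lab) -
            crf_log_likelihood(inst$S, crf_transitions(Tm, inst$start, inst$end), lab)) / (2 * eps)
    expect_equal(g$dTrans[k], num, tolerance = 1e-5)
  }
})

test_that("marginalized (masked) CRF likelihood sums over ignored labelings", {
  set.seed(17)
  inst <- random_crf_instance(4)
  tr <- crf_transitions(inst$trans, inst$start, inst$end)
  labels <- c("B", "IGNORE", "O", "IGNORE")
  got <- listqa:::crf_grad_marginalized(inst$S, tr, labels)
  # oracle: marginal probability of the constrained positions
  p <- enum_span_marginal(inst$S, inst$trans, inst$start, inst$end,
                          positions = c(1, 3), labels = c("B", "O"))
  expect_equal(got$loglik, log(p), tolerance = 1e-9)
})

test_that("viterbi: decoupled case, length-1, empty, determinism on ties", {
  set.seed(19)
  S <- matrix(rnorm(15), 5, 3)
  expect_equal(viterbi_decode(S)$path,
               c("B", "I", "O")[apply(S, 1, which.max)])
  s1 <- matrix(c(0.1, 0.9, 0.2), 1, 3)
  tr <- crf_transitions(start = c(0, 0, 1), end = numeric(3))
  got <- viterbi_decode(s1, tr)
  expect_equal(got$path, "O")                 # 0.2 + 1 beats 0.9
  expect_equal(got$score, 1.2)
  expect_equal(viterbi_decode(matrix(numeric(0), 0, 3))$path, character())
  # all-tied instance: lowest label index wins at the latest positions
  tied <- viterbi_decode(matrix(0, 3, 3))
  expect_equal(tied$path, c("B", "B", "B"))
})

test_that("training is reproducible and learns a separable toy set", {
  g <- generate_synthetic(synthetic_spec(n_questions = 50,
                                         answers_per_question = 1:2, seed = 23))
  tk <- word_tokenizer()
  samples <- prepare_samples(g$corpus, tk)
  expect_length(samples, 50)
  cfg <- train_config(head = "linear", lr = 0.05, max_steps = 60, seed = 4)
  m1 <- train_tagger(samples, cfg)
  m2 <- train_tagger(samples, cfg)
  expect_identical(m1$log, m2$log)            # determinism contract
  cfg2 <- train_config(head = "linear", lr = 0.05, max_steps = 300, seed = 4)
  m3 <- train_tagger(samples, cfg2)
  expect_lt(utils::tail(m3$log$loss, 1), 0.1) # learnability
})

test_that("config defaults follow the reference training setup", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 18L)
  expect_equal(cfg$lr, 5e-6)
  expect_equal(cfg$max_len, 512L)
})

test_that("BiLSTM and BiLSTM-CRF heads train end to end", {
  g <- generate_synthetic(synthetic_spec(n_questions = 12,
                                         answers_per_question = 2, seed = 29))
  tk <- word_tokenizer()
  samples <- prepare_samples(g$corpus, tk)
  for (head in c("bilstm", "bilstm_crf")) {
    cfg <- train_config(head = head, lr = 0.03, max_steps = 8, seed = 5,
                        dim = 8, hidden = 6, batch_size = 6)
    m <- train_tagger(samples, cfg)
    expect_equal(nrow(m$log), 8)
    expect_true(all(is.finite(m$log$loss)))
    if (head == "bilstm_crf") expect_s3_class(m$transitions, "crf_transitions")
  }
  # the marginalize switch for IGNORE positions also runs
  cfgm <- train_config(head = "bilstm_crf", lr = 0.03, max_steps = 3, seed = 5,
                       dim = 8, hidden = 6, batch_size = 6,
                       crf_ignore = "marginalize")
  expect_true(all(is.finite(train_tagger(samples, cfgm)$log$loss)))
})
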