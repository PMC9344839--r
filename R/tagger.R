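# Sequence-tagging heads over the encoder output: linear, BiLSTM, and
# BiLSTM-CRF. All gradients are analytic; the whole model trains on a CPU.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Construct a linear tagging head
#'
#' @param W D x 3 weight matrix (D = encoder output width).
#' @param b Length-3 bias.
#' @return A `linear_head` object.
#' @export
linear_head <- function(W, b = numeric(3)) {
  stopifnot(is.matrix(W), ncol(W) == 3L, length(b) == 3L)
  structure(list(type = "linear", W = W, b = b), class = "linear_head")
}

#' Construct a BiLSTM tagging head
#'
#' Each direction is a standard LSTM (gate order input, forget, cell,
#' output); the concatenated hidden states feed a linear projection to the
#' three labels.
#'
#' @param fwd,bwd Per-direction parameter lists with `Wx` (D x 4H), `Wh`
#'   (H x 4H) and `b` (length 4H).
#' @param W 2H x 3 projection weights.
#' @param b Length-3 projection bias.
#' @return A `bilstm_head` object.
#' @export
bilstm_head <- function(fwd, bwd, W, b = numeric(3)) {
  H <- ncol(fwd$Wh) / 4L
  stopifnot(nrow(W) == 2L * H, ncol(W) == 3L)
  structure(list(type = "bilstm", fwd = fwd, bwd = bwd, W = W, b = b,
                 hidden = as.integer(H)),
            class = "bilstm_head")
}

init_lstm_dir <- function(D, H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1                   # forget-gate bias
  list(Wx = matrix(stats::rnorm(D * 4L * H, sd = 1 / sqrt(D)), D, 4L * H),
       Wh = matrix(stats::rnorm(H * 4L * H, sd = 1 / sqrt(H)), H, 4L * H),
       b = b)
}

# One-direction LSTM forward over the rows of X. Returns hidden states and
# the caches needed for backpropagation through time.
lstm_forward <- function(par, X) {
  L <- nrow(X); H <- ncol(par$Wh) / 4L
  Hs <- matrix(0, L, H); Cs <- matrix(0, L, H)
  gates <- vector("list", L)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(L)) {
    z <- drop(X[t, ] %*% par$Wx) + drop(h %*% par$Wh) + par$b
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sigmoid(z[(3 * H + 1):(4 * H)])
    c_prev <- cc
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    Hs[t, ] <- h; Cs[t, ] <- cc
    gates[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tanh(cc))
  }
  list(H = Hs, C = Cs, gates = gates)
}

# Backprop through time; dH is the gradient wrt the hidden states.
lstm_backward <- function(par, X, cache, dH) {
  L <- nrow(X); H <- ncol(par$Wh) / 4L
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dX <- X * 0
  dh_carry <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(L))) {
    gt <- cache$gates[[t]]
    dh <- dH[t, ] + dh_carry
    do <- dh * gt$tc
    dct <- dh * gt$o * (1 - gt$tc^2) + dc_next
    di <- dct * gt$g; dg <- dct * gt$i; df <- dct * gt$c_prev
    dc_next <- dct * gt$f
    dz <- c(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
            dg * (1 - gt$g^2), do * gt$o * (1 - gt$o))
    dWx <- dWx + outer(X[t, ], dz)
    h_prev <- if (t > 1L) cache$H[t - 1L, ] else numeric(H)
    dWh <- dWh + outer(h_prev, dz)
    db <- db + dz
    dX[t, ] <- drop(par$Wx %*% dz)
    dh_carry <- drop(par$Wh %*% dz)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

#' Score tokens over the three tagging labels
#'
#' Applies a tagging head to the per-token encodings. The linear head is an
#' affine map per token (position-independent); the BiLSTM head runs a
#' bidirectional recurrent pass and projects the concatenated hidden states.
#' Deterministic given the head state.
#'
#' @param encodings L x D matrix of token representations.
#' @param head A [linear_head()] or [bilstm_head()] (a fitted
#'   [train_tagger()] model's `$head` also works).
#' @return L x 3 score matrix, columns B, I, O.
#' @export
score_tokens <- function(encodings, head) {
  stopifnot(is.matrix(encodings))
  if (inherits(head, "span_tagger")) head <- head$head
  if (head$type == "linear") {
    if (ncol(encodings) != nrow(head$W))
      stop("encoding width ", ncol(encodings), " does not match head (",
           nrow(head$W), ")")
    S <- encodings %*% head$W
    return(sweep(S, 2L, head$b, `+`))
  }
  if (ncol(encodings) != nrow(head$fwd$Wx))
    stop("encoding width does not match BiLSTM head input size")
  fw <- lstm_forward(head$fwd, encodings)
  bw <- lstm_forward(head$bwd, encodings[rev(seq_len(nrow(encodings))), ,
                                         drop = FALSE])
  Hcat <- cbind(fw$H, bw$H[rev(seq_len(nrow(encodings))), , drop = FALSE])
  sweep(Hcat %*% head$W, 2L, head$b, `+`)
}

# Head forward that also keeps caches for the backward pass.
head_forward <- function(head, X) {
  if (head$type == "linear")
    return(list(S = sweep(X %*% head$W, 2L, head$b, `+`)))
  ridx <- rev(seq_len(nrow(X)))
  fw <- lstm_forward(head$fwd, X)
  bw <- lstm_forward(head$bwd, X[ridx, , drop = FALSE])
  Hcat <- cbind(fw$H, bw$H[ridx, , drop = FALSE])
  list(S = sweep(Hcat %*% head$W, 2L, head$b, `+`),
       fw = fw, bw = bw, Hcat = Hcat, ridx = ridx)
}

head_backward <- function(head, X, cache, dS) {
  if (head$type == "linear")
    return(list(grads = list(W = crossprod(X, dS), b = colSums(dS)),
                dX = dS %*% t(head$W)))
  H <- head$hidden
  dW <- crossprod(cache$Hcat, dS)
  db <- colSums(dS)
  dHcat <- dS %*% t(head$W)
  dHf <- dHcat[, 1:H, drop = FALSE]
  dHb <- dHcat[, (H + 1):(2 * H), drop = FALSE][cache$ridx, , drop = FALSE]
  bf <- lstm_backward(head$fwd, X, cache$fw, dHf)
  Xr <- X[cache$ridx, , drop = FALSE]
  bb <- lstm_backward(head$bwd, Xr, cache$bw, dHb)
  dX <- bf$dX + bb$dX[cache$ridx, , drop = FALSE]
  list(grads = list(fWx = bf$dWx, fWh = bf$dWh, fb = bf$db,
                    bWx = bb$dWx, bWh = bb$dWh, bb = bb$db,
                    W = dW, b = db),
       dX = dX)
}

#' Masked cross-entropy loss
#'
#' Cross-entropy of the per-token label distribution, averaged over the
#' supervised positions only (labels in `{B, I, O}`). Positions labelled
#' `IGNORE` contribute exactly zero to the loss and to its gradient, so the
#' model is never penalized at special tokens, question tokens or sub-word
#' continuation pieces. Over a batch the documented reduction is the total
#' cross-entropy divided by the total supervised-token count (i.e. samples
#' are weighted by their number of supervised tokens).
#'
#' @param scores L x 3 score matrix (columns B, I, O).
#' @param labels Character vector over `{B, I, O, IGNORE}` of length L.
#' @return Non-negative scalar loss.
#' @export
masked_loss <- function(scores, labels) {
  masked_loss_grad(scores, labels)$loss
}

masked_loss_grad <- function(scores, labels) {
  stopifnot(is.matrix(scores), ncol(scores) == 3L,
            length(labels) == nrow(scores))
  sup <- which(labels %in% BIO_LABELS)
  if (length(sup) == 0L)
    stop("no supervised positions: every label is IGNORE")
  P <- softmax_rows(scores[sup, , drop = FALSE])
  y <- match(labels[sup], BIO_LABELS)
  ce <- -log(pmax(P[cbind(seq_along(sup), y)], .Machine$double.xmin))
  dS <- matrix(0, nrow(scores), 3L)
  G <- P
  G[cbind(seq_along(sup), y)] <- G[cbind(seq_along(sup), y)] - 1
  dS[sup, ] <- G                              # gradient of the *sum*; the
  list(loss = sum(ce) / length(sup),          # caller divides by the count
       ce_sum = sum(ce), n_sup = length(sup), dS_sum = dS)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference training setup for fine-tuning pretrained
#' encoders: batch size 18, target-stage learning rate 5e-6 (a transfer
#' pre-training stage conventionally uses 5e-5; run [train_tagger()] twice
#' for the two-stage schedule). The from-scratch tiny encoder used in tests
#' needs a much larger rate (e.g. 0.05), passed explicitly.
#'
#' @param head `"linear"`, `"bilstm"` or `"bilstm_crf"`.
#' @param lr Learning rate (Adam). Default 5e-6.
#' @param batch_size Minibatch size. Default 18.
#' @param max_steps Maximum optimizer steps. Default 1000.
#' @param seed Random seed; drives initialization, per-epoch shuffling and
#'   word dropout, and is recorded in the fitted model. Mandatory.
#' @param shuffle Reshuffle sample order at the start of each epoch.
#' @param dim,window,word_dropout Passed to [window_encoder()].
#' @param vocab_min_count Minimum training-corpus frequency for a token to
#'   get its own embedding; rarer tokens train as the unknown token, which
#'   is how unseen words present at prediction time (vocabulary pruning,
#'   the standard treatment for open-vocabulary entity mentions). Default 3.
#' @param hidden BiLSTM hidden size per direction. Default 16.
#' @param max_len Maximum input length in tokens. Default 512.
#' @param clip Global gradient-norm clip. Default 5.
#' @param crf_ignore How the CRF variant treats `IGNORE` positions:
#'   `"as_o"` (default, train on all positions with `IGNORE` mapped to `O` --
#'   masking is conventionally not applied with a CRF layer) or
#'   `"marginalize"` (true masking: maximize the marginal likelihood of the
#'   supervised labels, summing over all labelings of ignored positions).
#' @param strict_transitions Clamp forbidden BIO transitions in the CRF to
#'   `-Inf`. Default `FALSE`; decoding repairs orphan `I` labels instead.
#' @return A `train_config` object.
#' @export
train_config <- function(head = c("linear", "bilstm", "bilstm_crf"),
                         lr = 5e-6, batch_size = 18L, max_steps = 1000L,
                         seed = 1L, shuffle = TRUE,
                         dim = 16L, window = 1L, word_dropout = 0.1,
                         vocab_min_count = 3L,
                         hidden = 16L, max_len = 512L, clip = 5,
                         crf_ignore = c("as_o", "marginalize"),
                         strict_transitions = FALSE) {
  head <- match.arg(head)
  crf_ignore <- match.arg(crf_ignore)
  stopifnot(lr > 0, batch_size >= 1L, max_steps >= 1L, hidden >= 1L,
            is.numeric(seed), length(seed) == 1L)
  structure(list(head = head, lr = lr, batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), dim = as.integer(dim),
                 window = as.integer(window), word_dropout = word_dropout,
                 vocab_min_count = as.integer(vocab_min_count),
                 hidden = as.integer(hidden), max_len = as.integer(max_len),
                 clip = clip, crf_ignore = crf_ignore,
                 strict_transitions = isTRUE(strict_transitions)),
            class = "train_config")
}

# Flatten/restore parameter lists for the Adam update.
adam_init <- function(params) lapply(params, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] + lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

grad_global_norm <- function(grads) sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))

build_head_params <- function(config, D) {
  if (config$head == "linear") {
    list(W = matrix(stats::rnorm(D * 3L, sd = 1 / sqrt(D)), D, 3L),
         b = numeric(3L))
  } else {
    H <- config$hidden
    f <- init_lstm_dir(D, H); b <- init_lstm_dir(D, H)
    list(fWx = f$Wx, fWh = f$Wh, fb = f$b,
         bWx = b$Wx, bWh = b$Wh, bb = b$b,
         W = matrix(stats::rnorm(2L * H * 3L, sd = 1 / sqrt(2 * H)), 2L * H, 3L),
         b = numeric(3L))
  }
}

params_to_head <- function(config, params) {
  if (config$head == "linear") return(linear_head(params$W, params$b))
  bilstm_head(fwd = list(Wx = params$fWx, Wh = params$fWh, b = params$fb),
              bwd = list(Wx = params$bWx, Wh = params$bWh, b = params$bb),
              W = params$W, b = params$b)
}

head_param_names <- function(config) {
  if (config$head == "linear") c("W", "b")
  else c("fWx", "fWh", "fb", "bWx", "bWh", "bb", "W", "b")
}

#' Train a span tagger
#'
#' Minibatch gradient descent (Adam) over BIO-labelled samples. Training
#' samples are reshuffled at the start of each epoch; every source of
#' randomness (initialization, shuffling, word dropout) is driven by the
#' configured seed, so two runs with identical seed, config and data produce
#' identical training logs. A two-stage transfer schedule (pre-train on one
#' corpus at a higher rate, then continue on the target corpus at a lower
#' rate) is two successive calls, passing the first model as `init_model`.
#'
#' @param samples List of training samples, each a list with `tok` (a
#'   `tokenized_input`) and `labels` (output of [assign_bio_labels()]).
#'   At least one sample must have a supervised position.
#' @param config A [train_config()].
#' @param encoder An optional [window_encoder()] spec; by default built from
#'   `config`.
#' @param init_model Optional fitted `span_tagger` whose parameters and
#'   vocabulary warm-start this run (the transfer stage).
#' @return A `span_tagger` object: encoder state, head, CRF transitions
#'   (when applicable), config, and a training `log` data frame with
#'   columns `step`, `epoch`, `loss`.
#' @export
train_tagger <- function(samples, config, encoder = NULL, init_model = NULL) {
  stopifnot(inherits(config, "train_config"), length(samples) >= 1L)
  if (is.null(encoder))
    encoder <- window_encoder(dim = config$dim, window = config$window,
                              word_dropout = config$word_dropout)
  set.seed(config$seed)
  if (is.null(init_model)) {
    vocab <- build_vocab(lapply(samples, function(s) s$tok$tokens),
                         min_count = config$vocab_min_count)
    enc_state <- init_encoder(encoder, vocab)
    params <- c(list(E = enc_state$E), build_head_params(config, encoder$out_dim))
    if (config$head == "bilstm_crf")
      params <- c(params, list(trans = matrix(0, 3, 3), tstart = numeric(3),
                               tend = numeric(3)))
  } else {
    vocab <- init_model$vocab
    enc_state <- list(spec = encoder, vocab = vocab, E = init_model$params$E)
    params <- init_model$params
  }
  is_crf <- config$head == "bilstm_crf"
  head_cfg <- config
  if (is_crf) head_cfg$head <- "bilstm"       # scores come from the BiLSTM

  n <- length(samples)
  opt <- adam_init(params)
  log_step <- integer(); log_epoch <- integer(); log_loss <- numeric()
  step <- 0L; epoch <- 0L
  while (step < config$max_steps) {
    epoch <- epoch + 1L
    order_ <- if (config$shuffle) sample.int(n) else seq_len(n)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      if (step >= config$max_steps) break
      idx <- order_[b0:min(b0 + config$batch_size - 1L, n)]
      grads <- zero_like(params)
      ce_sum <- 0; sup_sum <- 0L; crf_nll <- 0
      for (si in idx) {
        s <- samples[[si]]
        enc_state$E <- params$E
        ids <- encoder_ids(enc_state, s$tok$tokens, train = TRUE)
        ef <- encoder_forward(enc_state, ids)
        hd <- params_to_head(head_cfg, params)
        hf <- head_forward(hd, ef$X)
        if (!is_crf) {
          ml <- masked_loss_grad(hf$S, s$labels)
          ce_sum <- ce_sum + ml$ce_sum; sup_sum <- sup_sum + ml$n_sup
          dS <- ml$dS_sum                     # normalized after the batch
        } else {
          tr <- crf_transitions(params$trans, params$tstart, params$tend,
                                strict = config$strict_transitions)
          L <- nrow(hf$S)
          if (config$crf_ignore == "as_o") {
            y <- match(s$labels, BIO_LABELS); y[is.na(y)] <- 3L
            cg <- crf_grad(hf$S, tr, y)
          } else {
            cg <- crf_grad_marginalized(hf$S, tr, s$labels)
          }
          crf_nll <- crf_nll - cg$loglik / L
          sc <- L * length(idx)               # batch loss: mean per-token NLL
          dS <- -cg$dS / sc
          grads$trans <- grads$trans - cg$dTrans / sc
          grads$tstart <- grads$tstart - cg$dStart / sc
          grads$tend <- grads$tend - cg$dEnd / sc
        }
        hb <- head_backward(hd, ef$X, hf, dS)
        for (nm in names(hb$grads))
          grads[[nm]] <- grads[[nm]] + hb$grads[[nm]]
        grads$E <- encoder_backward(enc_state, ef, hb$dX, grads$E)
      }
      if (!is_crf) {
        if (sup_sum == 0L) stop("batch without any supervised position")
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / sup_sum
        loss <- ce_sum / sup_sum
      } else {
        loss <- crf_nll / length(idx)
      }
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at step ", step + 1L)
      gn <- grad_global_norm(grads)
      if (is.finite(config$clip) && gn > config$clip)
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * (config$clip / gn)
      step <- step + 1L
      upd <- adam_step(params, lapply(grads, function(g) -g), opt,
                       lr = config$lr, t = step)
      params <- upd$params; opt <- upd$state
      log_step <- c(log_step, step); log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, loss)
    }
  }
  enc_state$E <- params$E
  transitions <- if (is_crf)
    crf_transitions(params$trans, params$tstart, params$tend,
                    strict = config$strict_transitions) else NULL
  structure(list(params = params, vocab = vocab, encoder = enc_state,
                 head = params_to_head(head_cfg, params),
                 transitions = transitions, config = config,
                 log = data.frame(step = log_step, epoch = log_epoch,
                                  loss = log_loss)),
            class = "span_tagger")
}

# Gradient of the marginal log-likelihood of the supervised labels,
# summing over all labelings of IGNORE positions: log Z(constrained) - log Z.
crf_grad_marginalized <- function(scores, tr, labels) {
  y <- match(labels, BIO_LABELS)              # NA at IGNORE positions
  Sc <- scores
  for (t in which(!is.na(y))) Sc[t, -y[t]] <- -Inf
  con <- crf_expectations(Sc, tr)
  unc <- crf_expectations(scores, tr)
  list(loglik = con$logZ - unc$logZ,
       dS = con$gamma - unc$gamma,
       dTrans = con$xi - unc$xi,
       dStart = con$gamma[1L, ] - unc$gamma[1L, ],
       dEnd = con$gamma[nrow(scores), ] - unc$gamma[nrow(scores), ])
}

# Forward-backward expectations: log-partition, unary marginals gamma and
# expected transition counts xi. Tolerates -Inf unary scores (masked labels).
crf_expectations <- function(scores, tr) {
  L <- nrow(scores)
  fw <- crf_forward(scores, tr)
  beta <- crf_backward_lattice(scores, tr)
  gamma <- exp(fw$alpha + beta - fw$logZ)
  gamma[!is.finite(gamma)] <- 0
  xi <- matrix(0, 3, 3)
  if (L > 1L) for (t in 1L:(L - 1L)) {
    pair <- outer(fw$alpha[t, ], scores[t + 1L, ] + beta[t + 1L, ], `+`) +
      tr$trans - fw$logZ
    pair[!is.finite(pair)] <- -Inf
    xi <- xi + exp(pair)
  }
  list(logZ = fw$logZ, gamma = gamma, xi = xi)
}

#' @export
print.span_tagger <- function(x, ...) {
  cat("<span_tagger> head=", x$config$head,
      " vocab=", length(x$vocab),
      " dim=", x$encoder$spec$dim, "x(2*", x$encoder$spec$window, "+1)",
      " steps=", nrow(x$log),
      " final loss=", signif(utils::tail(x$log$loss, 1), 4), "\n", sep = "")
  invisible(x)
}
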