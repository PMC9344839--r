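# A small trainable contextual encoder. The pluggable-encoder contract is:
# deterministic-given-state mapping from a tokenized input to one fixed-width
# real vector per token. Heavy pretrained transformer encoders satisfy the
# same contract but live outside this package; the in-package encoder is a
# context-window embedding model (the representation of token t is the
# concatenation of the embeddings of tokens t-w .. t+w), which trains in
# seconds on a CPU and is contextual enough for the tagging machinery and
# its tests to be exercised end to end.

PAD_ID <- 1L
UNK_ID <- 2L

#' Declare a context-window encoder
#'
#' @param dim Embedding dimension per token (default 16).
#' @param window Context half-width `w`; the per-token representation has
#'   `(2w+1)*dim` entries (default 1).
#' @param word_dropout Probability, during training only, of replacing a
#'   token id by the unknown id. This trains the unknown embedding in
#'   context so the model generalizes to out-of-vocabulary words (answer
#'   entities unseen in training); standard for small embedding taggers.
#'   Default 0.1.
#' @param cased If `FALSE` (default) the encoder expects lower-cased tokens
#'   and answer matching should run uncased.
#' @return An `encoder_spec` object.
#' @export
window_encoder <- function(dim = 16L, window = 1L, word_dropout = 0.1,
                           cased = FALSE) {
  stopifnot(dim >= 1L, window >= 0L, word_dropout >= 0, word_dropout <= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 word_dropout = word_dropout, cased = cased,
                 out_dim = as.integer((2L * window + 1L) * dim)),
            class = "encoder_spec")
}

#' Build a vocabulary from token sequences
#'
#' Ids 1 and 2 are reserved for the out-of-range pad and the unknown token.
#'
#' @param token_lists List of character vectors.
#' @param min_count Minimum occurrence count to enter the vocabulary.
#' @return Named integer vector mapping token to id.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  counts <- table(unlist(token_lists, use.names = FALSE))
  words <- names(counts)[counts >= min_count]
  words <- sort(words)                        # deterministic order
  ids <- seq_along(words) + 2L
  stats::setNames(c(PAD_ID, UNK_ID, ids), c("<pad>", "<unk>", words))
}

# Initialize encoder state (embedding table). Uses the current RNG stream.
init_encoder <- function(spec, vocab) {
  E <- matrix(stats::rnorm(length(vocab) * spec$dim, sd = 0.1),
              nrow = length(vocab), ncol = spec$dim)
  E[PAD_ID, ] <- 0
  list(spec = spec, vocab = vocab, E = E)
}

# Map tokens to ids; optionally apply word dropout (training only).
encoder_ids <- function(state, tokens, train = FALSE) {
  ids <- unname(state$vocab[tokens])
  ids[is.na(ids)] <- UNK_ID
  if (train && state$spec$word_dropout > 0) {
    drop <- stats::runif(length(ids)) < state$spec$word_dropout
    ids[drop] <- UNK_ID
  }
  ids
}

# Forward pass: L x (2w+1)*dim matrix of window-concatenated embeddings.
# Returns the matrix and the id layout needed for the backward pass.
encoder_forward <- function(state, ids) {
  L <- length(ids); w <- state$spec$window; d <- state$spec$dim
  offs <- -w:w
  idmat <- matrix(PAD_ID, nrow = L, ncol = length(offs))
  for (k in seq_along(offs)) {
    src <- seq_len(L) + offs[k]
    ok <- src >= 1L & src <= L
    idmat[ok, k] <- ids[src[ok]]
  }
  X <- matrix(0, nrow = L, ncol = state$spec$out_dim)
  for (k in seq_along(offs))
    X[, ((k - 1L) * d + 1L):(k * d)] <- state$E[idmat[, k], , drop = FALSE]
  list(X = X, idmat = idmat)
}

# Accumulate embedding gradients from dX into a gradient table shaped like E.
encoder_backward <- function(state, cache, dX, dE) {
  d <- state$spec$dim
  for (k in seq_len(ncol(cache$idmat))) {
    block <- dX[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
    agg <- rowsum(block, group = cache$idmat[, k])
    rows <- as.integer(rownames(agg))
    dE[rows, ] <- dE[rows, , drop = FALSE] + agg
  }
  dE[PAD_ID, ] <- 0                           # pad stays fixed at zero
  dE
}
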