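# Linear-chain CRF over the three tagging labels, entirely in log space.
# Label order is fixed as B = 1, I = 2, O = 3 throughout the package.

BIO_LABELS <- c("B", "I", "O")

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Construct CRF transition parameters
#'
#' @param trans 3x3 matrix of label-to-label transition scores (rows: from,
#'   columns: to), label order B, I, O.
#' @param start,end Length-3 vectors of start/end scores.
#' @param strict If `TRUE`, forbidden BIO transitions (start at I, O->I) are
#'   clamped to `-Inf`. Off by default: decoding repairs orphan I labels, so
#'   unconstrained transitions are learnable.
#' @return A `crf_transitions` object.
#' @export
crf_transitions <- function(trans = matrix(0, 3, 3), start = numeric(3),
                            end = numeric(3), strict = FALSE) {
  stopifnot(is.matrix(trans), all(dim(trans) == c(3L, 3L)),
            length(start) == 3L, length(end) == 3L)
  dimnames(trans) <- list(BIO_LABELS, BIO_LABELS)
  if (strict) {
    start[2] <- -Inf                          # sequence cannot open with I
    trans["O", "I"] <- -Inf                   # I must follow B or I
  }
  structure(list(trans = trans, start = stats::setNames(start, BIO_LABELS),
                 end = stats::setNames(end, BIO_LABELS), strict = strict),
            class = "crf_transitions")
}

as_crf_transitions <- function(transitions) {
  if (is.null(transitions)) return(crf_transitions())
  if (inherits(transitions, "crf_transitions")) return(transitions)
  if (is.matrix(transitions)) return(crf_transitions(trans = transitions))
  stop("transitions must be NULL, a 3x3 matrix or a crf_transitions object")
}

check_scores <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) == 3L)
  if (!all(is.finite(scores))) stop("non-finite token scores")
  scores
}

# Forward algorithm; returns the alpha lattice and the log-partition.
crf_forward <- function(scores, tr, allowed = NULL) {
  L <- nrow(scores)
  alpha <- matrix(-Inf, L, 3L)
  mask <- function(t, v) {
    if (is.null(allowed) || is.na(allowed[t])) return(v)
    out <- rep(-Inf, 3L); out[allowed[t]] <- v[allowed[t]]; out
  }
  alpha[1L, ] <- mask(1L, tr$start + scores[1L, ])
  if (L > 1L) for (t in 2L:L) {
    v <- vapply(1:3, function(y)
      logsumexp(alpha[t - 1L, ] + tr$trans[, y]) + scores[t, y], 0)
    alpha[t, ] <- mask(t, v)
  }
  list(alpha = alpha, logZ = logsumexp(alpha[L, ] + tr$end))
}

crf_backward_lattice <- function(scores, tr) {
  L <- nrow(scores)
  beta <- matrix(-Inf, L, 3L)
  beta[L, ] <- tr$end
  if (L > 1L) for (t in (L - 1L):1L)
    beta[t, ] <- vapply(1:3, function(y)
      logsumexp(tr$trans[y, ] + scores[t + 1L, ] + beta[t + 1L, ]), 0)
  beta
}

# Score of one labelled path (start + unary + transition + end terms).
crf_path_score <- function(scores, tr, y) {
  L <- nrow(scores)
  s <- tr$start[y[1L]] + tr$end[y[L]] + sum(scores[cbind(seq_len(L), y)])
  if (L > 1L) s <- s + sum(tr$trans[cbind(y[-L], y[-1L])])
  unname(s)
}

#' CRF log-likelihood of a label path
#'
#' Path score minus the log-partition; the partition is computed by the
#' forward algorithm in log space. Scores are unnormalized, so the
#' log-likelihood of the gold path is bounded above by 0 only in the sense
#' that the path score never exceeds the log-partition.
#'
#' @param scores L x 3 matrix of per-token label scores (columns B, I, O).
#' @param transitions A [crf_transitions()] object, a 3x3 matrix, or `NULL`
#'   for all-zero transitions.
#' @param labels Character vector over `{B, I, O}` of length L. `IGNORE`
#'   labels are not accepted here: the CRF trains on full paths (callers map
#'   `IGNORE` to `O` first; see [train_config()]).
#' @return The log-likelihood (a scalar).
#' @export
crf_log_likelihood <- function(scores, transitions, labels) {
  check_scores(scores)
  tr <- as_crf_transitions(transitions)
  y <- match(labels, BIO_LABELS)
  if (anyNA(y)) stop("labels must all be in {B, I, O} for CRF likelihood")
  if (length(y) != nrow(scores)) stop("labels/scores length mismatch")
  fw <- crf_forward(scores, tr)
  crf_path_score(scores, tr, y) - fw$logZ
}

# Gradient of the log-likelihood wrt scores, transitions, start, end:
# empirical counts minus expected counts from the forward-backward marginals.
crf_grad <- function(scores, tr, y) {
  L <- nrow(scores)
  e <- crf_expectations(scores, tr)
  dS <- -e$gamma
  dS[cbind(seq_len(L), y)] <- dS[cbind(seq_len(L), y)] + 1
  dTrans <- -e$xi
  if (L > 1L) for (t in 1L:(L - 1L))
    dTrans[y[t], y[t + 1L]] <- dTrans[y[t], y[t + 1L]] + 1
  dStart <- -e$gamma[1L, ]; dStart[y[1L]] <- dStart[y[1L]] + 1
  dEnd <- -e$gamma[L, ]; dEnd[y[L]] <- dEnd[y[L]] + 1
  list(loglik = crf_path_score(scores, tr, y) - e$logZ,
       dS = dS, dTrans = dTrans, dStart = dStart, dEnd = dEnd)
}

#' Viterbi decoding
#'
#' Exact maximum-scoring label path by dynamic programming. Ties are broken
#' deterministically: backtracking chooses the lowest label index at each
#' step, which prefers the lower label index at the latest position where
#' tied paths differ.
#'
#' @param scores L x 3 matrix of per-token label scores (columns B, I, O).
#' @param transitions A [crf_transitions()] object, a 3x3 matrix, or `NULL`
#'   for all-zero transitions (in which case the path is the per-token
#'   argmax).
#' @return A list with `path` (character labels) and `score` (the path
#'   score). An empty score matrix yields an empty path with score 0.
#' @export
viterbi_decode <- function(scores, transitions = NULL) {
  tr <- as_crf_transitions(transitions)
  if (length(scores) == 0L || nrow(scores) == 0L)
    return(list(path = character(), score = 0))
  check_scores(scores)
  L <- nrow(scores)
  delta <- matrix(-Inf, L, 3L)
  back <- matrix(NA_integer_, L, 3L)
  delta[1L, ] <- tr$start + scores[1L, ]
  if (L > 1L) for (t in 2L:L) for (y in 1:3) {
    cand <- delta[t - 1L, ] + tr$trans[, y]
    back[t, y] <- which.max(cand)             # lowest index on ties
    delta[t, y] <- cand[back[t, y]] + scores[t, y]
  }
  fin <- delta[L, ] + tr$end
  y <- integer(L)
  y[L] <- which.max(fin)
  if (L > 1L) for (t in (L - 1L):1L) y[t] <- back[t + 1L, y[t + 1L]]
  list(path = BIO_LABELS[y], score = unname(fin[y[L]]))
}

#' Marginal probability of a span labelling under the CRF
#'
#' Probability that the given positions carry exactly the given labels,
#' marginalizing over all other positions: the ratio of the constrained to
#' the unconstrained partition, computed with two forward passes.
#'
#' @param scores L x 3 score matrix.
#' @param transitions See [viterbi_decode()].
#' @param positions Integer vector of constrained positions.
#' @param labels Character labels (over `{B, I, O}`), parallel to
#'   `positions`.
#' @return Probability in `[0, 1]`.
#' @export
crf_span_marginal <- function(scores, transitions, positions, labels) {
  check_scores(scores)
  tr <- as_crf_transitions(transitions)
  y <- match(labels, BIO_LABELS)
  stopifnot(length(positions) == length(y), !anyNA(y),
            all(positions >= 1L), all(positions <= nrow(scores)))
  allowed <- rep(NA_integer_, nrow(scores))
  allowed[positions] <- y
  logZc <- crf_forward(scores, tr, allowed = allowed)$logZ
  logZ <- crf_forward(scores, tr)$logZ
  exp(logZc - logZ)
}
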