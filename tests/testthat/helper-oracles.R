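# Independent brute-force oracles. These deliberately avoid the package's
# own lattice code: path scores are summed term by term over explicitly
# enumerated label paths.

# all 3^L label paths as an integer matrix (rows = paths, labels 1..3)
enum_paths <- function(L) {
  as.matrix(expand.grid(rep(list(1:3), L), KEEP.OUT.ATTRS = FALSE))
}

enum_path_scores <- function(S, trans, start, end) {
  L <- nrow(S)
  P <- enum_paths(L)
  sc <- start[P[, 1]] + end[P[, L]]
  for (t in seq_len(L)) sc <- sc + S[t, ][P[, t]]
  if (L > 1) for (t in 1:(L - 1))
    sc <- sc + trans[cbind(P[, t], P[, t + 1])]
  list(paths = P, scores = sc)
}

enum_max_score <- function(S, trans, start, end) {
  max(enum_path_scores(S, trans, start, end)$scores)
}

enum_log_partition <- function(S, trans, start, end) {
  sc <- enum_path_scores(S, trans, start, end)$scores
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

# sum of path probabilities over paths carrying `labels` at `positions`
enum_span_marginal <- function(S, trans, start, end, positions, labels) {
  e <- enum_path_scores(S, trans, start, end)
  y <- match(labels, c("B", "I", "O"))
  keep <- rep(TRUE, nrow(e$paths))
  for (k in seq_along(positions))
    keep <- keep & e$paths[, positions[k]] == y[k]
  m <- max(e$scores)
  sum(exp(e$scores[keep] - m)) / sum(exp(e$scores - m))
}

# maximum bipartite matching between predictions and synonym groups,
# by exhaustive recursion (edge iff exact normalized match)
bf_max_matching <- function(preds, groups) {
  norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  edge <- outer(seq_along(preds), seq_along(groups),
                Vectorize(function(i, j) norm(preds[i]) %in% norm(groups[[j]])))
  rec <- function(i, used) {
    if (i > length(preds)) return(0L)
    best <- rec(i + 1L, used)                 # leave prediction i unmatched
    for (j in seq_along(groups))
      if (!used[j] && edge[i, j]) {
        used2 <- used; used2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used2))
      }
    best
  }
  if (length(preds) == 0L || length(groups) == 0L) return(0L)
  rec(1L, logical(length(groups)))
}

random_crf_instance <- function(L, scale = 2) {
  list(S = matrix(stats::runif(L * 3, -scale, scale), L, 3),
       trans = matrix(stats::runif(9, -scale, scale), 3, 3),
       start = stats::runif(3, -scale, scale),
       end = stats::runif(3, -scale, scale))
}
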