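# Independent oracles used to check the package's statistics. These are
# deliberately naive (enumeration, brute-force pair counting,
# Floyd-Warshall) and share no code with the implementation.

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) equally likely draws; elements 1..K are the successes
hyper_upper_enum <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# ROC-AUC by brute-force counting of concordant disease x normal pairs,
# ties counting 1/2
auc_brute <- function(score, labels) {
  pos <- score[labels == 1]
  neg <- score[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# all-pairs shortest paths from a cost matrix (Inf = no edge, 0 diagonal)
floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# random connected-ish weighted graph as an edge data frame
random_weighted_edges <- function(n_nodes, n_edges, nodes = sprintf("v%02d", seq_len(n_nodes))) {
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  data.frame(gene_a = a[keep], gene_b = b[keep],
             weight = runif(sum(keep), 0.5, 1),
             stringsAsFactors = FALSE)
}
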