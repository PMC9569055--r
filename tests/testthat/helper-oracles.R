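# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain dynamic programs, set arithmetic and
# exhaustive enumeration.

# LCS length by dynamic programming (for the edit-distance identity
# d_{1,1,2}(a, b) = nchar(a) + nchar(b) - 2 * LCS(a, b)).
oracle_lcs <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0 || m == 0) return(0)
  D <- matrix(0L, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- if (A[i] == B[j]) D[i, j] + 1L else max(D[i, j + 1], D[i + 1, j])
  }
  D[n + 1, m + 1]
}

# Weighted edit distance by its own DP (general costs).
oracle_edit_distance <- function(a, b, ci = 1, cd = 1, cs = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * cd
  D[1, ] <- (0:m) * ci
  if (n > 0 && m > 0) {
    for (i in 1:n) for (j in 1:m) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + cd, D[i + 1, j] + ci,
                             D[i, j] + if (A[i] == B[j]) 0 else cs)
    }
  }
  D[n + 1, m + 1]
}

# Set-based Jaccard.
oracle_jaccard <- function(u, v) {
  U <- which(u == 1)
  V <- which(v == 1)
  uni <- union(U, V)
  if (length(uni) == 0) return(0)
  length(intersect(U, V)) / length(uni)
}

# AUC as the probability that a positive outscores a negative, all pairs
# compared, ties counted one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Random DAG on n nodes: edges only from lower to higher index (acyclic by
# construction), each possible edge kept with probability p.
random_dag_edges <- function(n, p = 0.3) {
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) edges <- rbind(edges, c(paste0("n", i), paste0("n", j)))
  }
  if (is.null(edges)) edges <- matrix(c("n1", "n2"), ncol = 2)
  edges
}

# Shortest directed path length from every ancestor down to d, by exhaustive
# igraph distances on the DAG.
oracle_contributions <- function(edges, d, mu) {
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  dist <- igraph::distances(g, to = d, mode = "out")[, 1]
  dist <- dist[is.finite(dist)]
  mu^dist
}

random_binary_matrix <- function(n, m, p = 0.3, ensure_nonzero = TRUE) {
  v <- matrix(stats::rbinom(n * m, 1, p), n, m)
  if (ensure_nonzero && sum(v) == 0) v[1, 1] <- 1
  v
}

tiny_assoc <- function(values, rid = NULL, cid = NULL) {
  values <- as.matrix(values)
  if (is.null(rid)) rid <- paste0("c", seq_len(nrow(values)))
  if (is.null(cid)) cid <- paste0("d", seq_len(ncol(values)))
  association_matrix(values, rid, cid)
}

# A small but complete dataset for fast end-to-end runs.
small_synthetic <- function(seed = 1) {
  generate_dataset(synthetic_config(n_circ = 60, n_disease = 18, n_blocks = 3,
                                    seq_len = 40, seed = seed))
}
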