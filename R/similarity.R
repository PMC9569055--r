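# The five base similarity models:
#   CS  - circRNA sequence similarity from weighted Levenshtein distance
#   CF  - circRNA functional similarity (mean Jaccard over disease/GO/miRNA
#         association profiles)
#   CG  - circRNA Gaussian interaction profile (GIP) kernel over S_d rows
#   DG  - disease GIP kernel over S_d columns
#   DS1 - DAG semantic similarity, layer-decay contribution model
#   DS2 - DAG semantic similarity, term-rarity contribution model

#' Edit-cost scheme for the weighted Levenshtein distance
#'
#' Defaults follow the common nucleotide convention: insertion and deletion
#' cost 1, substitution costs 2 (a substitution is never cheaper than a
#' delete+insert, which ties the distance to the longest common subsequence).
#'
#' @param insert,delete,substitute non-negative costs.
#' @return an object of class `edit_costs`.
#' @export
edit_costs <- function(insert = 1, delete = 1, substitute = 2) {
  if (any(c(insert, delete, substitute) < 0)) stop("edit costs must be non-negative")
  structure(list(insert = insert, delete = delete, substitute = substitute),
            class = "edit_costs")
}

#' Parameters of the DAG semantic similarity models
#'
#' @param mu contribution decay per DAG layer, in (0, 1]; default 0.5.
#' @param log_base base of the rarity logarithm in the second model; default
#'   natural log.
#' @param ds2_denominator `"primed"` normalizes the second model by its own
#'   (rarity-weighted) contribution sums, keeping scores in \[0, 1\] with unit
#'   diagonal; `"as_printed"` normalizes by the first model's contribution
#'   sums, in which case scores may leave \[0, 1\].
#' @return an object of class `semantic_params`.
#' @export
semantic_params <- function(mu = 0.5, log_base = exp(1),
                            ds2_denominator = c("primed", "as_printed")) {
  if (!(mu > 0 && mu <= 1)) stop("mu must be in (0, 1]")
  if (!(log_base > 0) || log_base == 1) stop("log_base must be positive and != 1")
  structure(list(mu = mu, log_base = log_base,
                 ds2_denominator = match.arg(ds2_denominator)),
            class = "semantic_params")
}

#' Parameters of the GIP kernel
#'
#' @param bandwidth_convention `"as_printed"` sets the bandwidth to the mean
#'   squared profile norm and uses it as the multiplier of the squared
#'   distance; `"reciprocal"` uses its reciprocal (the usual GIP convention,
#'   which makes the kernel scale-free in the profile density).
#' @return an object of class `gip_params`.
#' @export
gip_params <- function(bandwidth_convention = c("as_printed", "reciprocal")) {
  structure(list(bandwidth_convention = match.arg(bandwidth_convention)),
            class = "gip_params")
}

#' Weighted Levenshtein distance
#'
#' Minimum total cost over insertion/deletion/substitution scripts turning
#' `a` into `b`. With the default costs (1, 1, 2) the distance equals
#' `nchar(a) + nchar(b) - 2 * LCS(a, b)`.
#'
#' @param a,b character strings (empty strings allowed).
#' @param costs an [edit_costs()].
#' @return non-negative number.
#' @export
levenshtein_distance <- function(a, b, costs = edit_costs()) {
  stopifnot(inherits(costs, "edit_costs"))
  as.numeric(utils::adist(a, b, costs = list(insertions = costs$insert,
                                             deletions = costs$delete,
                                             substitutions = costs$substitute)))
}

#' Normalized sequence similarity of two circRNAs
#'
#' `(l(a) + l(b) - d(a, b)) / (l(a) + l(b))` where `d` is the weighted
#' Levenshtein distance; 1 for identical strings, 0 for maximally distant
#' ones under the default costs.
#'
#' @param a,b non-empty nucleotide strings.
#' @param costs an [edit_costs()].
#' @return score in \[0, 1\] (for cost schemes bounded by delete+insert).
#' @export
sequence_similarity <- function(a, b, costs = edit_costs()) {
  la <- unname(nchar(a))
  lb <- unname(nchar(b))
  if (la == 0 || lb == 0) stop("sequence similarity is undefined for empty strings")
  (la + lb - levenshtein_distance(a, b, costs)) / (la + lb)
}

#' circRNA sequence similarity matrix (CS)
#'
#' Pairwise normalized Levenshtein similarity over all circRNAs that have a
#' sequence; entries involving a circRNA without a sequence are placeholder 0
#' (the fusion stage masks them via the FQ flag). Diagonal is 1 for covered
#' circRNAs.
#'
#' @param seqs a [sequence_set()].
#' @param ids circRNA identifiers in association-matrix row order.
#' @param costs an [edit_costs()].
#' @return a `sim_matrix` over `ids`.
#' @export
sequence_similarity_matrix <- function(seqs, ids, costs = edit_costs()) {
  stopifnot(inherits(seqs, "sequence_set"))
  n <- length(ids)
  values <- matrix(0, n, n)
  cov <- which(ids %in% seqs$coverage)
  if (length(cov) > 0) {
    s <- seqs$sequences[ids[cov]]
    d <- utils::adist(s, costs = list(insertions = costs$insert,
                                      deletions = costs$delete,
                                      substitutions = costs$substitute))
    len <- nchar(s)
    tot <- outer(len, len, `+`)
    values[cov, cov] <- (tot - d) / tot
  }
  similarity_matrix(values, ids)
}

#' Jaccard similarity of two binary profiles
#'
#' `|u AND v| / |u OR v|`; returns 0 when the union is empty, so the score is
#' always defined (a circRNA with no annotations has similarity 0 to
#' everything, including itself).
#'
#' @param u,v binary vectors of equal length.
#' @return score in \[0, 1\].
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) stop("jaccard: profiles must have equal length")
  inter <- sum(u == 1 & v == 1)
  uni <- sum(u == 1 | v == 1)
  if (uni == 0) return(0)
  inter / uni
}

# Pairwise Jaccard over the rows of a binary matrix; empty unions give 0.
.jaccard_rows <- function(m) {
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, `+`) - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  out
}

#' circRNA functional similarity matrix (CF)
#'
#' Mean of three Jaccard similarities between the circRNAs' binary association
#' profiles: diseases (rows of S_d), GO terms (rows of S_g) and miRNAs (rows
#' of S_m).
#'
#' @param Sd,Sg,Sm `assoc_matrix` objects sharing identical `row_ids`.
#' @return a `sim_matrix` over the circRNA identifiers.
#' @export
functional_similarity <- function(Sd, Sg, Sm) {
  stopifnot(inherits(Sd, "assoc_matrix"), inherits(Sg, "assoc_matrix"),
            inherits(Sm, "assoc_matrix"))
  if (!identical(Sd$row_ids, Sg$row_ids) || !identical(Sd$row_ids, Sm$row_ids)) {
    stop("functional similarity requires identical circRNA identifier lists")
  }
  cf <- (.jaccard_rows(Sd$values) + .jaccard_rows(Sg$values) +
           .jaccard_rows(Sm$values)) / 3
  similarity_matrix(cf, Sd$row_ids)
}

#' GIP kernel bandwidth
#'
#' Under `"as_printed"` the bandwidth is the mean squared profile norm,
#' `delta = (1/n) * sum(||profile_m||^2)`, used directly as the multiplier of
#' the squared profile distance. Under `"reciprocal"` it is
#' `n / sum(||profile_m||^2)`.
#'
#' @param profiles binary matrix, one profile per row.
#' @param params a [gip_params()].
#' @return positive bandwidth.
#' @export
gip_bandwidth <- function(profiles, params = gip_params()) {
  profiles <- as.matrix(profiles)
  ssq <- sum(profiles^2)
  if (ssq == 0) {
    stop("degenerate GIP bandwidth: all profiles are zero (kernel would be constant)")
  }
  n <- nrow(profiles)
  if (params$bandwidth_convention == "as_printed") ssq / n else n / ssq
}

#' GIP kernel similarity matrix (CG or DG)
#'
#' `K(m, n) = exp(-delta * ||profile_m - profile_n||^2)` with `delta` from
#' [gip_bandwidth()]. For the circRNA kernel the profiles are the rows of the
#' association matrix; for the disease kernel, its columns.
#'
#' @param profiles binary matrix, one interaction profile per row.
#' @param ids identifiers for the rows of `profiles`.
#' @param params a [gip_params()].
#' @return a `sim_matrix` with unit diagonal.
#' @export
gip_kernel <- function(profiles, ids, params = gip_params()) {
  profiles <- as.matrix(profiles)
  delta <- gip_bandwidth(profiles, params)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-delta * d2)
  diag(k) <- 1
  similarity_matrix(k, ids)
}

#' circRNA GIP kernel similarity (CG)
#'
#' @param Sd the circRNA-disease `assoc_matrix`.
#' @param params a [gip_params()].
#' @return a `sim_matrix` over circRNAs.
#' @export
circrna_gip <- function(Sd, params = gip_params()) {
  stopifnot(inherits(Sd, "assoc_matrix"))
  gip_kernel(Sd$values, Sd$row_ids, params)
}

#' Disease GIP kernel similarity (DG)
#'
#' @param Sd the circRNA-disease `assoc_matrix`.
#' @param params a [gip_params()].
#' @return a `sim_matrix` over diseases.
#' @export
disease_gip <- function(Sd, params = gip_params()) {
  stopifnot(inherits(Sd, "assoc_matrix"))
  gip_kernel(t(Sd$values), Sd$col_ids, params)
}

# Ancestor set of d (d plus everything reaching d along parent->child edges),
# as a character vector, plus each member's shortest downward distance to d.
.ancestor_set <- function(dag, d) {
  parents <- split(dag$edges[, 1], factor(dag$edges[, 2], levels = dag$nodes))
  dist <- c(0)
  names(dist) <- d
  frontier <- d
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (p in parents[[v]]) {
        if (!(p %in% names(dist))) {
          dist[p] <- dist[[v]] + 1
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

#' Layer-decay contribution of DAG terms to a disease
#'
#' The disease contributes 1 to itself; every other term `k` in the disease's
#' DAG (the disease plus its ancestors) contributes
#' `max(mu * G(k')) over children k' of k inside the DAG`, so contributions
#' decay by `mu` per layer along the steepest descending path.
#'
#' @param dag a `disease_dag`.
#' @param d a disease present in the DAG.
#' @param params a [semantic_params()].
#' @return named numeric vector mapping each term of the disease's DAG to its
#'   contribution.
#' @export
semantic_contribution <- function(dag, d, params = semantic_params()) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!(d %in% dag$nodes)) stop(sprintf("disease '%s' is not in the DAG", d))
  dist <- .ancestor_set(dag, d)
  nd <- names(dist)
  g <- numeric(length(nd))
  names(g) <- nd
  g[d] <- 1
  children <- split(dag$edges[, 2], factor(dag$edges[, 1], levels = dag$nodes))
  for (v in nd[order(dist)]) {
    if (v == d) next
    ch <- intersect(children[[v]], nd)
    g[v] <- params$mu * max(g[ch])
  }
  g
}

# Contribution maps for every covered disease; list keyed by disease id.
.contribution_maps <- function(dag, ids, params) {
  covered <- dag_covered(dag, ids)
  maps <- lapply(covered, semantic_contribution, dag = dag, params = params)
  names(maps) <- covered
  maps
}

#' DAG semantic similarity, layer-decay model (DS1)
#'
#' For diseases `m`, `n` with DAG term sets `N_m`, `N_n` and contribution maps
#' `G_m`, `G_n`, the score is
#' `sum over shared terms of (G_m(k) + G_n(k)) / (sum(G_m) + sum(G_n))`.
#' Pairs where either disease is absent from the DAG score placeholder 0 (the
#' fusion stage masks them via the FS flag).
#'
#' @param dag a `disease_dag`.
#' @param ids disease identifiers in association-matrix column order.
#' @param params a [semantic_params()].
#' @return a `sim_matrix` over `ids`.
#' @export
semantic_similarity_1 <- function(dag, ids, params = semantic_params()) {
  maps <- .contribution_maps(dag, ids, params)
  .semantic_pairs(ids, num_maps = maps, den_maps = maps)
}

#' DAG semantic similarity, term-rarity model (DS2)
#'
#' Terms are weighted by their rarity across the covered diseases' DAGs:
#' `G'(k) = log(n_diseases / n_DAGs_containing_k)` (so a term present in
#' every DAG contributes nothing). The pair score sums `G'` over shared terms
#' as in the first model. The denominator uses the rarity-weighted sums by
#' default (`ds2_denominator = "primed"`), or the first model's layer-decay
#' sums under `"as_printed"`. Zero denominators give 0.
#'
#' @param dag a `disease_dag`.
#' @param ids disease identifiers in association-matrix column order.
#' @param params a [semantic_params()].
#' @return a `sim_matrix` over `ids`.
#' @export
semantic_similarity_2 <- function(dag, ids, params = semantic_params()) {
  maps <- .contribution_maps(dag, ids, params)
  n_dis <- length(maps)
  if (n_dis == 0) return(similarity_matrix(matrix(0, length(ids), length(ids)), ids))
  term_counts <- table(unlist(lapply(maps, names)))
  gprime <- log(n_dis / as.numeric(term_counts)) / log(params$log_base)
  names(gprime) <- names(term_counts)
  primed <- lapply(maps, function(m) {
    v <- gprime[names(m)]
    names(v) <- names(m)
    v
  })
  den <- if (params$ds2_denominator == "primed") primed else maps
  .semantic_pairs(ids, num_maps = primed, den_maps = den)
}

# Shared pair loop for the two semantic models: score(m, n) =
# sum_{k in both}(num_m(k) + num_n(k)) / (sum(den_m) + sum(den_n)).
.semantic_pairs <- function(ids, num_maps, den_maps) {
  n <- length(ids)
  values <- matrix(0, n, n)
  covered <- names(num_maps)
  den_sums <- vapply(den_maps, sum, numeric(1))
  for (i in seq_len(n)) {
    di <- ids[i]
    if (!(di %in% covered)) next
    for (j in i:n) {
      dj <- ids[j]
      if (!(dj %in% covered)) next
      shared <- intersect(names(num_maps[[di]]), names(num_maps[[dj]]))
      den <- den_sums[[di]] + den_sums[[dj]]
      if (length(shared) == 0 || den == 0) next
      values[i, j] <- sum(num_maps[[di]][shared] + num_maps[[dj]][shared]) / den
      values[j, i] <- values[i, j]
    }
  }
  similarity_matrix(values, ids)
}
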