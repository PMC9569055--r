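test_that("weighted Levenshtein distance matches examples and the LCS identity", {
  expect_equal(levenshtein_distance("ACGT", "ACGT"), 0)
  expect_equal(levenshtein_distance("A", "G"), 2)       # one substitution
  expect_equal(levenshtein_distance("ACGT", "ACG"), 1)  # one deletion
  expect_error(edit_costs(insert = -1), "non-negative")

  # d_{1,1,2}(a, b) = l(a) + l(b) - 2 * LCS(a, b), LCS by independent DP
  set.seed(101)
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), replace = TRUE),
               collapse = "")
    expect_equal(levenshtein_distance(a, b),
                 nchar(a) + nchar(b) - 2 * oracle_lcs(a, b))
  }
})

test_that("edit distance honors non-default costs", {
  set.seed(5)
  costs <- edit_costs(insert = 1, delete = 2, substitute = 1.5)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(levenshtein_distance(a, b, costs),
                 oracle_edit_distance(a, b, ci = 1, cd = 2, cs = 1.5))
  }
})

test_that("sequence similarity follows the normalized-distance formula", {
  expect_equal(sequence_similarity("ACGT", "ACGT"), 1)
  expect_equal(sequence_similarity("A", "G"), 0)
  expect_equal(sequence_similarity("ACGT", "ACG"), 6 / 7)
  expect_error(sequence_similarity("", ""), "empty")

  # in [0,1], symmetric, 1 iff identical
  set.seed(31)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), replace = TRUE),
               collapse = "")
    s <- sequence_similarity(a, b)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, sequence_similarity(b, a))
    if (s == 1) expect_identical(a, b)
  }
})

test_that("sequence similarity matrix matches pairwise calls and masks gaps", {
  set.seed(17)
  ids <- paste0("c", 1:6)
  raw <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  }, character(1))
  names(raw) <- ids
  seqs <- sequence_set(raw[1:5], ids)  # c6 has no sequence
  CS <- sequence_similarity_matrix(seqs, ids)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(CS$values[i, j], sequence_similarity(raw[i], raw[j]))
  }
  expect_true(all(CS$values[6, ] == 0))
  expect_true(all(CS$values[, 6] == 0))
  expect_equal(diag(CS$values)[1:5], rep(1, 5), ignore_attr = TRUE)

  # identical sequences give an all-ones block
  same <- sequence_set(setNames(rep("ACGT", 3), ids[1:3]), ids)
  expect_true(all(sequence_similarity_matrix(same, ids)$values[1:3, 1:3] == 1))
})

test_that("jaccard equals the set oracle exhaustively on a 6-element universe", {
  expect_equal(jaccard(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard(c(1, 1), c(1, 1)), 1)
  expect_equal(jaccard(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard(c(0, 0), c(0, 0)), 0)  # empty union
  expect_error(jaccard(c(1, 0), c(1, 0, 1)), "length")

  subsets <- expand.grid(rep(list(0:1), 6))
  for (i in seq_len(nrow(subsets))) {
    u <- as.numeric(subsets[i, ])
    v <- as.numeric(subsets[(i * 7) %% nrow(subsets) + 1, ])
    expect_equal(jaccard(u, v), oracle_jaccard(u, v))
  }
})

test_that("functional similarity averages the three profile Jaccards", {
  set.seed(23)
  Sd <- tiny_assoc(random_binary_matrix(5, 8))
  Sg <- tiny_assoc(random_binary_matrix(5, 6), cid = paste0("g", 1:6))
  Sm <- tiny_assoc(random_binary_matrix(5, 7), cid = paste0("m", 1:7))
  CF <- functional_similarity(Sd, Sg, Sm)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(CF$values[i, j],
                 (oracle_jaccard(Sd$values[i, ], Sd$values[j, ]) +
                    oracle_jaccard(Sg$values[i, ], Sg$values[j, ]) +
                    oracle_jaccard(Sm$values[i, ], Sm$values[j, ])) / 3)
  }
  expect_error(functional_similarity(Sd, tiny_assoc(matrix(1, 4, 2),
                                                    rid = paste0("x", 1:4)), Sm),
               "identical circRNA identifier")
})

test_that("GIP bandwidth follows both conventions and rejects zero profiles", {
  expect_equal(gip_bandwidth(diag(2)), 1)                       # (1+1)/2
  expect_equal(gip_bandwidth(diag(2), gip_params("reciprocal")), 1)
  expect_error(gip_bandwidth(matrix(0, 3, 3)), "degenerate")
  m <- rbind(c(1, 1, 0), c(1, 0, 0))
  expect_equal(gip_bandwidth(m), 3 / 2)
  expect_equal(gip_bandwidth(m, gip_params("reciprocal")), 2 / 3)
})

test_that("GIP kernel matches the closed form, has unit diagonal, and is PSD", {
  K <- gip_kernel(diag(2), c("a", "b"))
  expect_equal(K$values[1, 2], exp(-2))
  expect_equal(diag(K$values), c(a = 1, b = 1))

  set.seed(91)
  for (i in 1:5) {
    prof <- random_binary_matrix(20, 12)
    prof[sample(20, 2), ] <- prof[1, ]  # identical rows anywhere -> entry 1
    K <- gip_kernel(prof, paste0("e", 1:20))
    expect_true(all(abs(K$values - t(K$values)) < 1e-12))
    expect_gte(min(eigen(K$values, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    same <- which(apply(prof, 1, identical, prof[1, ]))
    expect_true(all(K$values[same, same] == 1))
  }
})

test_that("semantic contributions decay as mu^(shortest path)", {
  chain <- disease_dag(rbind(c("r", "a"), c("a", "d")))
  g <- semantic_contribution(chain, "d")
  expect_equal(g[["d"]], 1)
  expect_equal(g[["a"]], 0.5)
  expect_equal(g[["r"]], 0.25)

  diamond <- disease_dag(rbind(c("r", "a"), c("r", "b"), c("a", "d"), c("b", "d")))
  g <- semantic_contribution(diamond, "d")
  expect_equal(g[["r"]], 0.25)  # max over two equal-length paths

  expect_error(semantic_contribution(chain, "zz"), "not in the DAG")

  # property: G_d(k) = mu^(shortest directed path k -> d) on random DAGs
  set.seed(77)
  for (rep in 1:60) {
    edges <- random_dag_edges(sample(4:12, 1), p = 0.35)
    dag <- disease_dag(edges)
    leaves <- setdiff(dag$nodes, edges[, 1])
    d <- if (length(leaves) > 0) sample(leaves, 1) else sample(dag$nodes, 1)
    mu <- sample(c(0.3, 0.5, 0.8), 1)
    got <- semantic_contribution(dag, d, semantic_params(mu = mu))
    want <- oracle_contributions(edges, d, mu)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("first semantic model matches hand-evaluated scores and its invariants", {
  dag <- disease_dag(rbind(c("r", "a"), c("r", "b"), c("a", "d1"), c("b", "d2")))
  DS1 <- semantic_similarity_1(dag, c("d1", "d2", "d3"))
  expect_equal(DS1$values["d1", "d1"], 1)
  expect_equal(DS1$values["d1", "d2"], (0.25 + 0.25) / (1.75 + 1.75))  # = 1/7
  expect_true(all(DS1$values["d3", ] == 0))  # uncovered disease

  # disjoint DAGs share no node
  dag2 <- disease_dag(rbind(c("r1", "d1"), c("r2", "d2")))
  expect_equal(semantic_similarity_1(dag2, c("d1", "d2"))$values["d1", "d2"], 0)

  # in [0,1], symmetric, unit diagonal on covered diseases
  set.seed(13)
  for (rep in 1:20) {
    edges <- random_dag_edges(8, 0.3)
    dag <- disease_dag(edges)
    ids <- sample(dag$nodes, 4)
    DS1 <- semantic_similarity_1(dag, ids)
    expect_true(all(DS1$values >= 0 & DS1$values <= 1))
    expect_equal(DS1$values, t(DS1$values))
    expect_equal(diag(DS1$values), setNames(rep(1, 4), ids))
  }
})

test_that("second semantic model weights terms by rarity", {
  # two-disease universe: shared root has G' = log(2/2) = 0
  dag <- disease_dag(rbind(c("r", "a"), c("r", "b"), c("a", "d1"), c("b", "d2")))
  DS2 <- semantic_similarity_2(dag, c("d1", "d2"))
  expect_equal(DS2$values["d1", "d2"], 0)
  expect_equal(DS2$values["d1", "d1"], 1)  # primed denominator normalizes

  # as_printed denominator uses the layer-decay sums instead
  DS2p <- semantic_similarity_2(dag, c("d1", "d2"),
                                semantic_params(ds2_denominator = "as_printed"))
  expect_equal(DS2p$values["d1", "d1"], 2 * (log(2) + log(2)) / (2 * 1.75))

  # log base is configurable
  DS2b <- semantic_similarity_2(dag, c("d1", "d2"),
                                semantic_params(log_base = 2,
                                                ds2_denominator = "as_printed"))
  expect_equal(DS2b$values["d1", "d1"], 2 * (1 + 1) / (2 * 1.75))
})
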