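test_that("negative sampling is balanced, disjoint from positives, and seeded", {
  set.seed(2)
  Sd <- tiny_assoc(random_binary_matrix(10, 10, p = 0.2))
  ds <- sample_negatives(Sd, seed = 5)
  n_pos <- sum(Sd$values)
  expect_equal(sum(ds$labels == 1), n_pos)
  expect_equal(sum(ds$labels == 0), n_pos)    # balanced by default
  neg <- ds$pairs[ds$labels == 0, , drop = FALSE]
  expect_true(all(Sd$values[neg] == 0))
  pos <- ds$pairs[ds$labels == 1, , drop = FALSE]
  expect_true(all(Sd$values[pos] == 1))

  expect_identical(sample_negatives(Sd, seed = 5)$pairs, ds$pairs)
  # different seeds give different draws essentially always
  diffs <- vapply(1:100, function(s) {
    !identical(sample_negatives(Sd, seed = 1000 + s)$pairs, ds$pairs)
  }, logical(1))
  expect_gt(mean(diffs), 0.95)

  expect_error(sample_negatives(Sd, n = 1e6), "zero cells")
})

test_that("stratified k-fold split yields balanced disjoint covering folds", {
  labels <- rep(c(1L, 0L), each = 1194)  # 2388 samples
  ds <- pair_dataset(cbind(seq_along(labels), 1L), labels)
  folds <- kfold_split(ds, k = 5, seed = 3)
  sizes <- sort(vapply(folds, function(f) length(f$validation), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(478L, 478L, 478L, 477L, 477L))
  all_val <- unlist(lapply(folds, `[[`, "validation"))
  expect_equal(sort(all_val), seq_along(labels))        # disjoint cover
  for (f in folds) {
    expect_equal(sort(c(f$train, f$validation)), seq_along(labels))
    frac_pos <- mean(labels[f$validation])
    expect_lt(abs(frac_pos - 0.5), 0.01)                # stratification
  }
  expect_identical(kfold_split(ds, k = 5, seed = 3), folds)
  expect_error(kfold_split(ds, k = 5000), "exceeds")
})

test_that("independent split reproduces the 20% protocol arithmetic", {
  labels <- rep(c(1L, 0L), each = 1492)  # 2984 samples
  ds <- pair_dataset(cbind(seq_along(labels), 1L), labels)
  sp <- independent_split(ds, fraction = 0.2, seed = 2)
  expect_equal(length(sp$holdout), 596L)
  expect_equal(length(sp$working), 2388L)
  expect_length(intersect(sp$holdout, sp$working), 0)
  # label proportions preserved within one sample
  expect_lte(abs(sum(labels[sp$holdout]) - 0.2 * 1492), 1)
  expect_error(independent_split(ds, fraction = 0), "fraction")
})

test_that("metrics match brute-force confusion counts and the pairwise AUC oracle", {
  set.seed(44)
  for (rep in 1:200) {
    n <- sample(10:40, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), 2)  # rounding forces ties
    thr <- stats::runif(1)
    rec <- compute_metrics(labels, scores, threshold = thr)
    pred <- as.integer(scores >= thr)
    expect_equal(rec$confusion[["TP"]], sum(pred & labels))
    expect_equal(rec$confusion[["FP"]], sum(pred & !labels))
    expect_equal(rec$confusion[["TN"]], sum(!pred & !labels))
    expect_equal(rec$confusion[["FN"]], sum(!pred & labels))
    expect_equal(sum(rec$confusion), n)
    expect_equal(rec$auc, oracle_auc(labels, scores))
    expect_equal(rec$accuracy, mean(pred == labels))
    if (!is.na(rec$f1)) {
      expect_equal(rec$f1, 2 * rec$precision * rec$recall /
                     (rec$precision + rec$recall), tolerance = 1e-9)
    }
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(55)
  labels <- sample(0:1, 50, replace = TRUE, prob = c(0.5, 0.5))
  labels[1:2] <- c(0L, 1L)
  scores <- stats::rnorm(50)
  a0 <- compute_metrics(labels, scores)$auc
  expect_equal(compute_metrics(labels, exp(scores))$auc, a0)
  expect_equal(compute_metrics(labels, 10 + 3 * scores)$auc, a0)
  expect_equal(compute_metrics(labels, stats::pnorm(scores))$auc, a0)
})

test_that("perfect separation and degenerate labels behave as specified", {
  rec <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(rec$auc, 1)
  expect_equal(rec$accuracy, 1)
  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)), "single class")
})

test_that("fold averaging is the arithmetic mean of per-fold records", {
  recs <- lapply(c(0.9903, 0.9924, 0.9908, 0.9879, 0.9907), function(a) {
    structure(list(auc = a, accuracy = a, precision = a, recall = a, f1 = a,
                   confusion = c(TP = 1, FP = 0, TN = 1, FN = 0)),
              class = "metrics_record")
  })
  avg <- summarize_folds(recs)
  expect_equal(avg$auc, mean(c(0.9903, 0.9924, 0.9908, 0.9879, 0.9907)))
  expect_equal(avg$confusion[["TP"]], 5)
})

test_that("ROC points trace the empirical curve", {
  labels <- c(1, 0, 1, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.2)
  pts <- roc_points(labels, scores)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoid area equals the rank AUC
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(area, compute_metrics(labels, scores)$auc)
})

test_that("candidate ranking equals the brute-force sort on a small fixture", {
  data <- generate_worked_example()
  feats <- build_features(data$Sd, data$Sg, data$Sm, data$seqs, data$dag)
  cfg <- model_config(highorder_dim = 8, tower_hidden = c(8, 8),
                      head_hidden = c(8, 4), epochs = 20, batch_size = 4,
                      seed = 11)
  ds <- sample_negatives(data$Sd, seed = 12)
  model <- train_model(feats$CV, feats$DV, ds, cfg)

  ranking <- rank_candidates(model, data$Sd, feats$CV, feats$DV, top_k = 5)
  zero <- which(data$Sd$values == 0, arr.ind = TRUE)
  scores <- predict_pairs(model, feats$CV, feats$DV, zero)
  ord <- order(-scores, zero[, 1], zero[, 2])[1:5]
  expect_equal(ranking$circrna, data$Sd$row_ids[zero[ord, 1]])
  expect_equal(ranking$disease, data$Sd$col_ids[zero[ord, 2]])
  expect_equal(ranking$score, scores[ord])
  expect_true(all(diff(ranking$score) <= 0))
  # no known positive leaks into the candidate list
  known <- paste(data$Sd$row_ids[which(data$Sd$values == 1, arr.ind = TRUE)[, 1]],
                 data$Sd$col_ids[which(data$Sd$values == 1, arr.ind = TRUE)[, 2]])
  expect_length(intersect(paste(ranking$circrna, ranking$disease), known), 0)

  expect_warning(all14 <- rank_candidates(model, data$Sd, feats$CV, feats$DV,
                                          top_k = 1000), "exceeds")
  expect_equal(nrow(all14), sum(data$Sd$values == 0))
})

test_that("cross-validation runs end-to-end, is reproducible, and reports k folds", {
  data <- small_synthetic(seed = 7)
  cfg <- model_config(highorder_dim = 16, tower_hidden = c(32, 16),
                      head_hidden = c(16, 8), epochs = 30, seed = 1)
  res1 <- run_cross_validation(data$Sd, data$Sg, data$Sm, data$seqs, data$dag,
                               model_config = cfg, k = 3, seed = 5)
  res2 <- run_cross_validation(data$Sd, data$Sg, data$Sm, data$seqs, data$dag,
                               model_config = cfg, k = 3, seed = 5)
  expect_length(res1$folds, 3)
  expect_identical(vapply(res1$folds, `[[`, numeric(1), "auc"),
                   vapply(res2$folds, `[[`, numeric(1), "auc"))
  expect_equal(res1$average$auc,
               mean(vapply(res1$folds, `[[`, numeric(1), "auc")))
  # the planted structure is learnable even at this reduced size
  expect_gt(res1$average$auc, 0.7)
})

test_that("strict mode recomputes kernels without the validation positives", {
  data <- small_synthetic(seed = 9)
  cfg <- model_config(highorder_dim = 8, tower_hidden = c(16, 8),
                      head_hidden = c(8, 4), epochs = 10, seed = 2)
  res_strict <- run_cross_validation(data$Sd, data$Sg, data$Sm, data$seqs,
                                     data$dag, model_config = cfg, k = 3,
                                     seed = 5, strict = TRUE)
  res_leaky <- run_cross_validation(data$Sd, data$Sg, data$Sm, data$seqs,
                                    data$dag, model_config = cfg, k = 3,
                                    seed = 5, strict = FALSE)
  expect_length(res_strict$folds, 3)
  # the kernels really are recomputed: fold scores differ from the
  # full-matrix pipeline on the same seed and folds
  expect_false(identical(res_strict$predictions[[1]]$score,
                         res_leaky$predictions[[1]]$score))
  # but the shared (non-GIP) features keep the two runs on the same dataset
  expect_identical(res_strict$dataset$pairs, res_leaky$dataset$pairs)
})

test_that("baseline harness mirrors the CV schema for each classifier", {
  data <- small_synthetic(seed = 3)
  feats <- build_features(data$Sd, data$Sg, data$Sm, data$seqs, data$dag)
  ds <- sample_negatives(data$Sd, seed = 8)
  X <- cascade_features(feats$CV, feats$DV, ds$pairs)
  expect_equal(ncol(X), nrow(feats$CV$values) + nrow(feats$DV$values))

  for (spec in c("forest", "feedforward")) {
    res <- run_baseline(X, ds$labels, spec, k = 3, seed = 4)
    expect_length(res$folds, 3)
    expect_named(res$average[c("auc", "accuracy", "precision", "recall", "f1")],
                 c("auc", "accuracy", "precision", "recall", "f1"))
    expect_gt(res$average$auc, 0.5)
  }
  expect_error(run_baseline(X, ds$labels, "boosting"), "arg")
})
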