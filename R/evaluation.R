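# Evaluation protocol: balanced negative sampling, stratified k-fold
# cross-validation, an independent holdout split, the metric suite
# (AUC / accuracy / precision / recall / F1), a baseline-classifier harness
# and unknown-pair ranking.

#' Construct a labeled pair dataset
#'
#' @param pairs two-column integer matrix of (circRNA index, disease index).
#' @param labels 0/1 vector, one per pair.
#' @param provenance optional list of sampling metadata (seed etc.).
#' @return an object of class `pair_dataset`.
#' @export
pair_dataset <- function(pairs, labels, provenance = list()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  labels <- as.integer(labels)
  if (nrow(pairs) != length(labels)) stop("pairs and labels differ in length")
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (anyDuplicated(pairs)) stop("duplicate pairs in dataset")
  structure(list(pairs = pairs, labels = labels, provenance = provenance),
            class = "pair_dataset")
}

#' Balanced negative sampling
#'
#' Takes every known association as a positive example and draws `n`
#' unverified (zero) cells uniformly at random without replacement as
#' negatives; by default `n` equals the positive count, giving a balanced
#' dataset.
#'
#' @param Sd the circRNA-disease `assoc_matrix`.
#' @param n number of negatives; default = number of positives.
#' @param seed integer seed.
#' @return a `pair_dataset` with positives first, then negatives.
#' @export
sample_negatives <- function(Sd, n = NULL, seed = 1) {
  stopifnot(inherits(Sd, "assoc_matrix"))
  pos <- which(Sd$values == 1, arr.ind = TRUE)
  zero <- which(Sd$values == 0, arr.ind = TRUE)
  if (is.null(n)) n <- nrow(pos)
  if (n > nrow(zero)) {
    stop(sprintf("requested %d negatives but only %d zero cells available",
                 n, nrow(zero)))
  }
  set.seed(seed)
  neg <- zero[sample.int(nrow(zero), n), , drop = FALSE]
  pair_dataset(rbind(pos, neg),
               c(rep(1L, nrow(pos)), rep(0L, n)),
               provenance = list(seed = seed, n_negative = n))
}

#' Stratified k-fold split
#'
#' Partitions the dataset into k folds whose sizes differ by at most one,
#' stratified by label (each class is spread as evenly as possible, and the
#' classes' remainder folds are staggered so the overall sizes stay within
#' one of each other).
#'
#' @param dataset a `pair_dataset`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratified stratify by label (default TRUE).
#' @return list of k elements, each `list(train = <indices>, validation =
#'   <indices>)`; every index appears in exactly one validation set.
#' @export
kfold_split <- function(dataset, k = 5, seed = 1, stratified = TRUE) {
  stopifnot(inherits(dataset, "pair_dataset"))
  n <- length(dataset$labels)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the dataset size")
  set.seed(seed)
  fold_of <- integer(n)
  groups <- if (stratified) split(seq_len(n), dataset$labels) else list(seq_len(n))
  offset <- 0L
  for (g in groups) {
    g <- g[sample.int(length(g))]
    m <- length(g)
    base <- m %/% k
    rem <- m %% k
    # remainder folds continue where the previous class stopped, keeping
    # overall fold sizes within one of each other
    sizes <- rep(base, k)
    if (rem > 0) {
      extra <- ((offset + seq_len(rem) - 1L) %% k) + 1L
      sizes[extra] <- sizes[extra] + 1L
      offset <- (offset + rem) %% k
    }
    fold_of[g] <- rep.int(seq_len(k), sizes)
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), validation = which(fold_of == f))
  })
}

#' Stratified independent holdout split
#'
#' Reserves `floor(fraction * n)` samples as a disjoint holdout set,
#' stratified by label (per-class counts allocated by largest remainder).
#'
#' @param dataset a `pair_dataset`.
#' @param fraction holdout proportion in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return `list(working = <indices>, holdout = <indices>)`.
#' @export
independent_split <- function(dataset, fraction = 0.2, seed = 1) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- length(dataset$labels)
  n_hold <- floor(fraction * n)
  if (n_hold < 1 || n_hold >= n) stop("degenerate split sizes")
  set.seed(seed)
  groups <- split(seq_len(n), dataset$labels)
  targets <- vapply(groups, function(g) fraction * length(g), numeric(1))
  take <- floor(targets)
  short <- n_hold - sum(take)
  if (short > 0) {
    frac_part <- targets - take
    bump <- order(frac_part, decreasing = TRUE)[seq_len(short)]
    take[bump] <- take[bump] + 1
  }
  holdout <- unlist(mapply(function(g, t) {
    g[sample.int(length(g), t)]
  }, groups, take, SIMPLIFY = FALSE), use.names = FALSE)
  holdout <- sort(holdout)
  list(working = setdiff(seq_len(n), holdout), holdout = holdout)
}

#' Classification and ranking metrics
#'
#' Confusion counts are taken at `score >= threshold`; accuracy is
#' `(TP + TN) / total`, precision `TP / (TP + FP)`, recall `TP / (TP + FN)`,
#' F1 the harmonic mean of precision and recall. AUC uses the rank statistic
#' (probability that a positive outscores a negative, ties counted one half).
#' Undefined ratios (empty denominators) are reported as `NA`.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @param threshold classification cutoff (default 0.5).
#' @return an object of class `metrics_record` with fields `auc`, `accuracy`,
#'   `precision`, `recall`, `f1` and `confusion` (TP, FP, TN, FN).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC is undefined with a single class")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(auc = auc,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision,
                 recall = recall,
                 f1 = f1_score(precision, recall),
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "metrics_record")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * precision * recall / (precision + recall)`; `NA` when
#' either input is `NA` or both are zero.
#'
#' @param precision,recall values in \[0, 1\].
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("AUC %.4f | acc %.4f | prec %.4f | rec %.4f | F1 %.4f\n",
              x$auc, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Average per-fold metrics
#'
#' @param records list of `metrics_record` objects.
#' @return a `metrics_record` of arithmetic means (confusion counts summed).
#' @export
summarize_folds <- function(records) {
  pick <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  structure(list(auc = mean(pick("auc")),
                 accuracy = mean(pick("accuracy")),
                 precision = mean(pick("precision")),
                 recall = mean(pick("recall")),
                 f1 = mean(pick("f1")),
                 confusion = Reduce(`+`, lapply(records, `[[`, "confusion"))),
            class = "metrics_record")
}

#' Build all similarity matrices and fuse them
#'
#' Runs the full similarity pipeline: CS from sequences, CF from the three
#' annotation matrices, CG/DG GIP kernels from the association matrix, DS1 and
#' DS2 from the disease DAG, then the flag-gated fusion into CV and DV.
#'
#' @param Sd,Sg,Sm association matrices (disease / GO / miRNA columns).
#' @param seqs a `sequence_set` (may cover only part of the circRNAs).
#' @param dag a `disease_dag` (may cover only part of the diseases).
#' @param costs an [edit_costs()].
#' @param gip a [gip_params()].
#' @param semantic a [semantic_params()].
#' @return list with elements CS, CF, CG, DG, DS1, DS2, FQ, FS, CV, DV.
#' @export
build_features <- function(Sd, Sg, Sm, seqs, dag, costs = edit_costs(),
                           gip = gip_params(), semantic = semantic_params()) {
  CS <- sequence_similarity_matrix(seqs, Sd$row_ids, costs)
  CF <- functional_similarity(Sd, Sg, Sm)
  CG <- circrna_gip(Sd, gip)
  DG <- disease_gip(Sd, gip)
  DS1 <- semantic_similarity_1(dag, Sd$col_ids, semantic)
  DS2 <- semantic_similarity_2(dag, Sd$col_ids, semantic)
  FQ <- build_sequence_flags(seqs, Sd$row_ids)
  FS <- build_semantic_flags(dag, Sd$col_ids)
  list(CS = CS, CF = CF, CG = CG, DG = DG, DS1 = DS1, DS2 = DS2,
       FQ = FQ, FS = FS,
       CV = fuse_circrna(CS, CF, CG, FQ),
       DV = fuse_disease(DS1, DS2, DG, FS))
}

# Recompute the GIP-dependent features with the given fold's validation
# positives removed from Sd (strict mode: no validation signal reaches the
# kernels).
.strict_features <- function(Sd, features, val_pos_pairs, gip) {
  vals <- Sd$values
  vals[val_pos_pairs] <- 0
  if (sum(vals) == 0) stop("strict mode: training fold has no positive association")
  Sd_train <- association_matrix(vals, Sd$row_ids, Sd$col_ids)
  CG <- circrna_gip(Sd_train, gip)
  DG <- disease_gip(Sd_train, gip)
  list(CV = fuse_circrna(features$CS, features$CF, CG, features$FQ),
       DV = fuse_disease(features$DS1, features$DS2, DG, features$FS))
}

#' Five-fold cross-validation of the full pipeline
#'
#' Builds the fused similarity matrices once from the complete association
#' matrix (mirroring the original pipeline order; note this lets kernel
#' features see held-out positives), samples balanced negatives, splits into
#' stratified folds, trains the network on each training portion and scores
#' the corresponding validation portion. `strict = TRUE` instead recomputes
#' the GIP kernels per fold with the validation positives zeroed out of the
#' association matrix, closing that leak at extra cost.
#'
#' @param Sd,Sg,Sm association matrices.
#' @param seqs a `sequence_set`.
#' @param dag a `disease_dag`.
#' @param model_config a [model_config()].
#' @param k number of folds (default 5).
#' @param seed seed for sampling/splitting (model seed comes from
#'   `model_config`, offset per fold).
#' @param threshold classification cutoff for the threshold metrics.
#' @param strict recompute GIP kernels from training folds only.
#' @param costs,gip,semantic similarity options.
#' @return list with `folds` (per-fold `metrics_record`s), `average`
#'   (their mean), `dataset`, and `features`.
#' @export
run_cross_validation <- function(Sd, Sg, Sm, seqs, dag,
                                 model_config = mspcd::model_config(),
                                 k = 5, seed = 1, threshold = 0.5,
                                 strict = FALSE,
                                 costs = edit_costs(), gip = gip_params(),
                                 semantic = semantic_params()) {
  features <- build_features(Sd, Sg, Sm, seqs, dag, costs, gip, semantic)
  dataset <- sample_negatives(Sd, seed = seed)
  folds <- kfold_split(dataset, k = k, seed = seed + 1L)
  records <- vector("list", k)
  predictions <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$validation
    feats <- features
    if (strict) {
      val_pos <- dataset$pairs[va[dataset$labels[va] == 1L], , drop = FALSE]
      feats <- c(features, .strict_features(Sd, features, val_pos, gip))
      feats <- feats[!duplicated(names(feats), fromLast = TRUE)]
    }
    cfg <- model_config
    cfg$seed <- model_config$seed + f
    model <- train_model(feats$CV, feats$DV,
                         pair_dataset(dataset$pairs[tr, , drop = FALSE],
                                      dataset$labels[tr]),
                         cfg)
    scores <- predict_pairs(model, feats$CV, feats$DV,
                            dataset$pairs[va, , drop = FALSE])
    records[[f]] <- compute_metrics(dataset$labels[va], scores, threshold)
    predictions[[f]] <- data.frame(fold = f,
                                   circrna = Sd$row_ids[dataset$pairs[va, 1]],
                                   disease = Sd$col_ids[dataset$pairs[va, 2]],
                                   label = dataset$labels[va],
                                   score = scores,
                                   stringsAsFactors = FALSE)
  }
  list(folds = records, average = summarize_folds(records),
       dataset = dataset, features = features, predictions = predictions)
}

#' ROC curve points
#'
#' Sweeps the score thresholds and returns one (FPR, TPR) point per distinct
#' score, plus the (0, 0) and (1, 1) endpoints.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  keep <- !duplicated(scores, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(labels)[keep]
  fp <- cumsum(1 - labels)[keep]
  data.frame(fpr = c(0, fp / sum(labels == 0), 1),
             tpr = c(0, tp / sum(labels == 1), 1))
}

#' Baseline-classifier cross-validation
#'
#' Replaces the hierarchical network with a classical classifier on the
#' cascaded features `[CV row; DV row]` of each pair, under the same
#' stratified k-fold protocol: `"forest"` = random forest, `"margin"` =
#' support vector machine with probability outputs, `"feedforward"` =
#' single-hidden-layer neural network.
#'
#' @param features numeric matrix, one cascaded feature row per pair.
#' @param labels 0/1 vector.
#' @param classifier_spec `"forest"`, `"margin"` or `"feedforward"`.
#' @param k number of folds.
#' @param seed integer seed.
#' @param threshold classification cutoff.
#' @return list with `folds` and `average` as in [run_cross_validation()].
#' @export
run_baseline <- function(features, labels,
                         classifier_spec = c("forest", "margin", "feedforward"),
                         k = 5, seed = 1, threshold = 0.5) {
  classifier_spec <- match.arg(classifier_spec)
  labels <- as.integer(labels)
  ds <- pair_dataset(cbind(seq_along(labels), rep(1L, length(labels))), labels)
  folds <- kfold_split(ds, k = k, seed = seed + 1L)
  records <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$validation
    set.seed(seed + 100L + f)
    Xtr <- features[tr, , drop = FALSE]
    Xva <- features[va, , drop = FALSE]
    ytr <- labels[tr]
    scores <- switch(classifier_spec,
      forest = {
        fit <- randomForest::randomForest(Xtr, factor(ytr, levels = c(0, 1)),
                                          ntree = 200)
        stats::predict(fit, Xva, type = "prob")[, "1"]
      },
      margin = {
        fit <- e1071::svm(Xtr, factor(ytr, levels = c(0, 1)), probability = TRUE)
        attr(stats::predict(fit, Xva, probability = TRUE),
             "probabilities")[, "1"]
      },
      feedforward = {
        # single hidden layer kept small: nnet optimizes full-batch BFGS,
        # whose cost grows quickly with the weight count
        fit <- nnet::nnet(Xtr, ytr, size = 8, decay = 1e-4, maxit = 100,
                          entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
        as.numeric(stats::predict(fit, Xva))
      })
    records[[f]] <- compute_metrics(labels[va], scores, threshold)
  }
  list(folds = records, average = summarize_folds(records))
}

#' Cascaded pair features for baseline classifiers
#'
#' @param cv,dv fused `sim_matrix` inputs.
#' @param pairs two-column index matrix.
#' @return matrix with `nc + nd` columns (CV row then DV row per pair).
#' @export
cascade_features <- function(cv, dv, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  cbind(cv$values[pairs[, 1], , drop = FALSE],
        dv$values[pairs[, 2], , drop = FALSE])
}

#' Rank unknown circRNA-disease pairs
#'
#' Scores every zero cell of the association matrix with the trained model and
#' returns the `top_k` highest-scoring candidates; ties are broken by
#' (row index, column index) ascending for reproducible output.
#'
#' @param model a trained `mspcd_model`.
#' @param Sd the `assoc_matrix` whose zero cells are candidates.
#' @param cv,dv fused similarity matrices.
#' @param top_k number of candidates to return (default 15).
#' @return data.frame with columns `circrna`, `disease`, `score`, ordered by
#'   decreasing score.
#' @export
rank_candidates <- function(model, Sd, cv, dv, top_k = 15) {
  stopifnot(inherits(Sd, "assoc_matrix"))
  zero <- which(Sd$values == 0, arr.ind = TRUE)
  if (top_k > nrow(zero)) {
    warning(sprintf("top_k %d exceeds the %d unknown pairs; returning all",
                    top_k, nrow(zero)))
    top_k <- nrow(zero)
  }
  scores <- predict_pairs(model, cv, dv, zero)
  ord <- order(-scores, zero[, 1], zero[, 2])[seq_len(top_k)]
  data.frame(circrna = Sd$row_ids[zero[ord, 1]],
             disease = Sd$col_ids[zero[ord, 2]],
             score = scores[ord],
             stringsAsFactors = FALSE)
}

#' Write fold metrics as TSV
#'
#' One row per fold plus an `average` row, columns AUC/accuracy/precision/
#' recall/F1.
#'
#' @param result output of [run_cross_validation()] or [run_baseline()].
#' @param path output file.
#' @export
write_metrics <- function(result, path) {
  recs <- c(result$folds, list(result$average))
  df <- data.frame(
    fold = c(seq_along(result$folds), "average"),
    auc = vapply(recs, `[[`, numeric(1), "auc"),
    accuracy = vapply(recs, `[[`, numeric(1), "accuracy"),
    precision = vapply(recs, `[[`, numeric(1), "precision"),
    recall = vapply(recs, `[[`, numeric(1), "recall"),
    f1 = vapply(recs, `[[`, numeric(1), "f1"))
  utils::write.table(format(df, digits = 17), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
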