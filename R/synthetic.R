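# Synthetic dataset with planted cluster structure.
#
# circRNAs and diseases are partitioned into paired blocks; associations are
# dense within a paired block and sparse across blocks, each circRNA cluster
# descends from a common ancestor sequence by point mutation, annotations are
# drawn mostly from per-cluster vocabularies, and the disease DAG is a tree
# whose subtrees group same-cluster diseases. Every stage of the pipeline is
# therefore learnable from the generated data, and coverage gaps (circRNAs
# without sequences, diseases outside the DAG) exercise the fusion fallbacks.

#' Synthetic dataset configuration
#'
#' @param n_circ number of circRNAs.
#' @param n_disease number of diseases.
#' @param n_blocks number of paired circRNA/disease clusters.
#' @param p_in within-block association probability.
#' @param p_out cross-block association probability (must be < `p_in`).
#' @param seq_len length of each cluster's ancestor sequence (nt).
#' @param mutation_rate per-base substitution probability applied to cluster
#'   members' copies of the ancestor.
#' @param n_go,n_mirna annotation vocabulary sizes.
#' @param annotations_per_entity annotations drawn per circRNA per source.
#' @param frac_no_sequence fraction of circRNAs lacking a sequence.
#' @param frac_no_dag fraction of diseases absent from the DAG.
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_circ = 300, n_disease = 40, n_blocks = 6,
                             p_in = 0.30, p_out = 0.01, seq_len = 100,
                             mutation_rate = 0.05, n_go = 120, n_mirna = 80,
                             annotations_per_entity = 5,
                             frac_no_sequence = 0.1, frac_no_dag = 0.1,
                             seed = 1) {
  props <- c(p_in, p_out, mutation_rate, frac_no_sequence, frac_no_dag)
  if (any(props < 0 | props > 1)) stop("probabilities must lie in [0, 1]")
  if (p_out >= p_in) stop("p_out must be smaller than p_in")
  if (min(n_circ, n_disease) < n_blocks) stop("cluster sizes below 1")
  structure(list(n_circ = n_circ, n_disease = n_disease, n_blocks = n_blocks,
                 p_in = p_in, p_out = p_out, seq_len = seq_len,
                 mutation_rate = mutation_rate, n_go = n_go,
                 n_mirna = n_mirna,
                 annotations_per_entity = annotations_per_entity,
                 frac_no_sequence = frac_no_sequence,
                 frac_no_dag = frac_no_dag, seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                   collapse = "")

.mutate_seq <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
    }
  }
  paste(bases, collapse = "")
}

# Draw k annotation columns, 80% from the block's pool and 20% background.
.draw_annotations <- function(pool, vocab_size, k) {
  picks <- integer(0)
  for (i in seq_len(k)) {
    picks <- c(picks, if (stats::runif(1) < 0.8) sample(pool, 1) else sample.int(vocab_size, 1))
  }
  unique(picks)
}

#' Generate a synthetic dataset
#'
#' @param config a [synthetic_config()].
#' @return list with elements `Sd`, `seqs`, `Sg`, `Sm`, `dag`,
#'   `circ_blocks`, `disease_blocks` (ground-truth cluster labels).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nb <- config$n_blocks
  circ_ids <- sprintf("circ_%04d", seq_len(config$n_circ))
  dis_ids <- sprintf("disease_%03d", seq_len(config$n_disease))
  circ_blocks <- rep_len(seq_len(nb), config$n_circ)
  circ_blocks <- sort(circ_blocks)
  dis_blocks <- sort(rep_len(seq_len(nb), config$n_disease))

  # association matrix: Bernoulli block model
  same <- outer(circ_blocks, dis_blocks, `==`)
  p <- ifelse(same, config$p_in, config$p_out)
  vals <- matrix(stats::rbinom(length(p), 1, p), nrow = config$n_circ)
  if (sum(vals) == 0) vals[1, 1] <- 1
  # every row/column needs a defined GIP profile direction; leave as drawn
  Sd <- association_matrix(vals, circ_ids, dis_ids)

  # sequences: per-block ancestor, point-mutated copies; a fraction missing
  ancestors <- vapply(seq_len(nb), function(b) .random_seq(config$seq_len),
                      character(1))
  seqs <- vapply(seq_len(config$n_circ), function(i) {
    .mutate_seq(ancestors[circ_blocks[i]], config$mutation_rate)
  }, character(1))
  names(seqs) <- circ_ids
  n_missing <- round(config$frac_no_sequence * config$n_circ)
  if (n_missing > 0) seqs <- seqs[-sample.int(config$n_circ, n_missing)]
  seqs <- sequence_set(seqs, circ_ids)

  # GO / miRNA annotations from per-block pools plus background
  make_annot <- function(vocab_size, prefix) {
    pool_size <- max(1, floor(vocab_size / nb))
    pools <- lapply(seq_len(nb), function(b) {
      ((b - 1) * pool_size + 1):min(b * pool_size, vocab_size)
    })
    m <- matrix(0, config$n_circ, vocab_size)
    for (i in seq_len(config$n_circ)) {
      cols <- .draw_annotations(pools[[circ_blocks[i]]], vocab_size,
                                config$annotations_per_entity)
      m[i, cols] <- 1
    }
    if (sum(m) == 0) m[1, 1] <- 1
    association_matrix(m, circ_ids, sprintf("%s_%03d", prefix, seq_len(vocab_size)))
  }
  Sg <- make_annot(config$n_go, "go")
  Sm <- make_annot(config$n_mirna, "mir")

  # disease DAG: root -> block ancestors -> random tree over covered diseases
  n_nodag <- round(config$frac_no_dag * config$n_disease)
  uncovered <- if (n_nodag > 0) sample.int(config$n_disease, n_nodag) else integer(0)
  edges <- matrix(character(0), ncol = 2)
  for (b in seq_len(nb)) {
    anc <- sprintf("anc_%02d", b)
    edges <- rbind(edges, c("anc_root", anc))
    members <- setdiff(which(dis_blocks == b), uncovered)
    placed <- character(0)
    for (m in members) {
      parent <- if (length(placed) == 0 || stats::runif(1) < 0.5) {
        anc
      } else {
        sample(placed, 1)
      }
      edges <- rbind(edges, c(parent, dis_ids[m]))
      placed <- c(placed, dis_ids[m])
    }
  }
  dag <- disease_dag(edges)

  list(Sd = Sd, seqs = seqs, Sg = Sg, Sm = Sm, dag = dag,
       circ_blocks = circ_blocks, disease_blocks = dis_blocks,
       config = config)
}

#' Write a generated dataset to a directory
#'
#' Emits the four inputs in the standard formats consumed by the readers:
#' `associations.tsv`, `go.tsv`, `mirna.tsv` (dense 0/1 grids, which preserve
#' entities without any association), `sequences.fasta` and `dag.tsv`.
#'
#' @param data output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_dense(data$Sd, file.path(dir, "associations.tsv"))
  write_fasta(data$seqs, file.path(dir, "sequences.fasta"))
  write_association_dense(data$Sg, file.path(dir, "go.tsv"))
  write_association_dense(data$Sm, file.path(dir, "mirna.tsv"))
  write_dag(data$dag, file.path(dir, "dag.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `Sd`, `seqs`, `Sg`, `Sm`, `dag`.
#' @export
read_dataset <- function(dir) {
  Sd <- read_association_table(file.path(dir, "associations.tsv"), "dense")
  list(Sd = Sd,
       seqs = read_fasta(file.path(dir, "sequences.fasta"), Sd$row_ids),
       Sg = read_association_table(file.path(dir, "go.tsv"), "dense"),
       Sm = read_association_table(file.path(dir, "mirna.tsv"), "dense"),
       dag = read_dag(file.path(dir, "dag.tsv")))
}

#' Miniature worked example
#'
#' A fixed 5-circRNA x 4-disease dataset small enough to verify every
#' similarity by hand: `circ_d` has no sequence (exercising the FQ fallback),
#' `dis_w` is absent from the DAG (exercising FS), and `circ_e` has no GO
#' annotations (exercising the empty-union Jaccard rule).
#'
#' @return list with the same fields as [generate_dataset()] minus the block
#'   labels.
#' @export
generate_worked_example <- function() {
  circ_ids <- c("circ_a", "circ_b", "circ_c", "circ_d", "circ_e")
  dis_ids <- c("dis_t", "dis_u", "dis_v", "dis_w")
  Sd <- association_matrix(rbind(
    c(1, 1, 0, 0),   # circ_a
    c(1, 0, 0, 0),   # circ_b
    c(0, 0, 1, 0),   # circ_c
    c(0, 0, 1, 1),   # circ_d
    c(0, 0, 0, 1)),  # circ_e
    circ_ids, dis_ids)
  seqs <- sequence_set(c(circ_a = "ACGTACGT", circ_b = "ACGTACGA",
                         circ_c = "TTTTCCCC", circ_e = "ACGTTCGT"),
                       circ_ids)
  Sg <- association_matrix(rbind(
    c(1, 1, 0),
    c(1, 0, 0),
    c(0, 0, 1),
    c(0, 1, 1),
    c(0, 0, 0)),
    circ_ids, c("go_1", "go_2", "go_3"))
  Sm <- association_matrix(rbind(
    c(1, 0, 0),
    c(1, 1, 0),
    c(0, 0, 1),
    c(0, 0, 1),
    c(0, 1, 0)),
    circ_ids, c("mir_1", "mir_2", "mir_3"))
  dag <- disease_dag(rbind(
    c("root", "node_a"), c("root", "node_b"),
    c("node_a", "dis_t"), c("node_a", "dis_u"), c("node_b", "dis_v")))
  list(Sd = Sd, seqs = seqs, Sg = Sg, Sm = Sm, dag = dag)
}
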