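# Flag-gated fusion of the base similarities into the model inputs:
#   CV(m, n) = (CS + CF) / 2 where both circRNAs have sequences, else CG
#   DV(m, n) = (DS1 + DS2) / 2 where both diseases are DAG-covered, else DG

#' Construct a binary flag matrix
#'
#' @param values binary square matrix.
#' @param ids ordered identifiers.
#' @return an object of class `flag_matrix`.
#' @export
flag_matrix <- function(values, ids) {
  values <- as.matrix(values)
  ids <- trimws(as.character(ids))
  if (nrow(values) != ncol(values) || length(ids) != nrow(values)) {
    stop("flag matrix must be square and match its identifier list")
  }
  if (any(values != 0 & values != 1)) stop("flag matrix entries must be 0 or 1")
  if (max(abs(values - t(values))) > 0) stop("flag matrix must be symmetric")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids), class = "flag_matrix")
}

#' Sequence-availability flags (FQ)
#'
#' `FQ(m, n) = 1` iff both circRNAs have a sequence; the diagonal follows the
#' same rule, so a circRNA without a sequence is GIP-backed even against
#' itself.
#'
#' @param seqs a `sequence_set`.
#' @param ids circRNA identifiers in association-matrix row order.
#' @return a `flag_matrix`.
#' @export
build_sequence_flags <- function(seqs, ids) {
  stopifnot(inherits(seqs, "sequence_set"))
  has <- as.numeric(ids %in% seqs$coverage)
  flag_matrix(outer(has, has), ids)
}

#' Semantic-availability flags (FS)
#'
#' `FS(m, n) = 1` iff both diseases appear in the DAG.
#'
#' @param dag a `disease_dag`.
#' @param ids disease identifiers in association-matrix column order.
#' @return a `flag_matrix`.
#' @export
build_semantic_flags <- function(dag, ids) {
  stopifnot(inherits(dag, "disease_dag"))
  has <- as.numeric(ids %in% dag_covered(dag, ids))
  flag_matrix(outer(has, has), ids)
}

.check_shared_ids <- function(..., what) {
  mats <- list(...)
  ids <- mats[[1]]$ids
  for (m in mats[-1]) {
    if (!identical(m$ids, ids)) {
      stop(sprintf("%s: inputs must share the same identifiers in the same order", what))
    }
  }
  ids
}

#' Fused circRNA similarity (CV)
#'
#' Where the sequence flag is set, the average of sequence and functional
#' similarity; elsewhere the circRNA GIP kernel.
#'
#' @param CS,CF,CG `sim_matrix` inputs over the same circRNA ids.
#' @param FQ a `flag_matrix` from [build_sequence_flags()].
#' @return a `sim_matrix`.
#' @export
fuse_circrna <- function(CS, CF, CG, FQ) {
  ids <- .check_shared_ids(CS, CF, CG, FQ, what = "fuse_circrna")
  v <- ifelse(FQ$values == 1, (CS$values + CF$values) / 2, CG$values)
  similarity_matrix(v, ids)
}

#' Fused disease similarity (DV)
#'
#' Where the semantic flag is set, the average of the two DAG semantic
#' similarities; elsewhere the disease GIP kernel. Under the `as_printed`
#' second-model convention entries can exceed 1; they are not clipped, but a
#' warning reports the maximum.
#'
#' @param DS1,DS2,DG `sim_matrix` inputs over the same disease ids.
#' @param FS a `flag_matrix` from [build_semantic_flags()].
#' @return a `sim_matrix`.
#' @export
fuse_disease <- function(DS1, DS2, DG, FS) {
  ids <- .check_shared_ids(DS1, DS2, DG, FS, what = "fuse_disease")
  v <- ifelse(FS$values == 1, (DS1$values + DS2$values) / 2, DG$values)
  if (max(v) > 1 + 1e-12) {
    warning(sprintf("fused disease similarity exceeds 1 (max %.6g); values are not clipped",
                    max(v)))
  }
  similarity_matrix(v, ids)
}
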