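# Core data containers and file I/O.
#
# Conventions shared by every stage:
#  * association matrices are oriented rows = circRNAs, columns = second
#    entity (diseases, GO terms or miRNAs);
#  * identifiers are matched exactly (case-sensitive) after trimming
#    surrounding whitespace;
#  * all tabular artifacts are plain TSV.

#' Construct a binary association matrix
#'
#' Container for a binary circRNA x entity association table, e.g. the
#' circRNA-disease matrix and the circRNA-GO / circRNA-miRNA annotation
#' matrices.
#'
#' @param values numeric or integer matrix containing only 0/1 entries.
#' @param row_ids character vector of circRNA identifiers (one per row).
#' @param col_ids character vector of column identifiers (diseases, GO terms
#'   or miRNAs).
#' @return an object of class `assoc_matrix` with fields `values`, `row_ids`,
#'   `col_ids`.
#' @export
association_matrix <- function(values, row_ids, col_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  row_ids <- trimws(as.character(row_ids))
  col_ids <- trimws(as.character(col_ids))
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids)) {
    stop("association matrix dimensions do not match identifier lists")
  }
  if (anyDuplicated(row_ids)) stop("duplicate row identifiers in association matrix")
  if (anyDuplicated(col_ids)) stop("duplicate column identifiers in association matrix")
  if (any(!is.finite(values)) || any(values != 0 & values != 1)) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  if (sum(values) == 0) stop("association matrix has no nonzero entry")
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d x %d, %d associations (density %.4f)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              association_density(x)))
  invisible(x)
}

#' Association density of a binary matrix
#'
#' Fraction of cells that are 1, i.e. `n_associations / (n_rows * n_cols)`.
#'
#' @param m an `assoc_matrix`.
#' @return a number in (0, 1].
#' @export
association_density <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"))
  mean(m$values)
}

#' Construct a sequence set
#'
#' Holds nucleotide sequences keyed by circRNA identifier. Records whose
#' identifier is not among `known_ids` are dropped with a warning; sequence
#' coverage may be partial (the fusion stage falls back to the GIP kernel for
#' uncovered pairs).
#'
#' @param sequences named character vector of nucleotide strings.
#' @param known_ids circRNA identifiers from the association matrix rows.
#' @return an object of class `sequence_set` with fields `sequences` (named,
#'   uppercased) and `coverage` (identifiers that have a sequence).
#' @export
sequence_set <- function(sequences, known_ids) {
  known_ids <- trimws(as.character(known_ids))
  if (length(sequences) == 0) {
    return(structure(list(sequences = character(0), coverage = character(0)),
                     class = "sequence_set"))
  }
  ids <- trimws(names(sequences))
  if (is.null(ids) || any(ids == "")) stop("every sequence needs an identifier")
  seqs <- toupper(as.character(sequences))
  if (any(nchar(seqs) == 0)) {
    stop(sprintf("empty sequence for identifier '%s'", ids[which(nchar(seqs) == 0)[1]]))
  }
  unknown <- !(ids %in% known_ids)
  if (any(unknown)) {
    warning(sprintf("dropping %d sequence record(s) with unknown identifiers (e.g. '%s')",
                    sum(unknown), ids[unknown][1]))
    seqs <- seqs[!unknown]
    ids <- ids[!unknown]
  }
  if (anyDuplicated(ids)) stop("duplicate sequence identifiers")
  names(seqs) <- ids
  structure(list(sequences = seqs, coverage = ids), class = "sequence_set")
}

#' Construct a disease DAG
#'
#' Directed acyclic graph of disease terms with edges oriented parent ->
#' child. The graph may contain terms (e.g. internal hierarchy nodes) that are
#' not diseases of the association matrix; coverage is resolved per analysis.
#'
#' @param edges two-column character matrix/data.frame of (parent, child)
#'   pairs; may have zero rows.
#' @param nodes optional extra isolated node identifiers.
#' @return an object of class `disease_dag` with fields `nodes` and `edges`.
#' @export
disease_dag <- function(edges, nodes = character(0)) {
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("DAG edges must be (parent, child) pairs")
    edges[] <- trimws(edges)
  }
  colnames(edges) <- c("parent", "child")
  nodes <- unique(c(trimws(as.character(nodes)), as.vector(edges)))
  nodes <- nodes[nodes != ""]
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
    bad <- edges[edges[, 1] == edges[, 2], , drop = FALSE][1, 1]
    stop(sprintf("self-loop on node '%s'", bad))
  }
  cyc <- .find_cycle(nodes, edges)
  if (!is.null(cyc)) {
    stop(sprintf("graph contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }
  structure(list(nodes = nodes, edges = edges), class = "disease_dag")
}

# Kahn's algorithm; returns NULL if acyclic, else one cycle as a node path.
.find_cycle <- function(nodes, edges) {
  if (length(nodes) == 0 || nrow(edges) == 0) return(NULL)
  idx <- seq_along(nodes)
  names(idx) <- nodes
  from <- idx[edges[, 1]]
  to <- idx[edges[, 2]]
  indeg <- tabulate(to, nbins = length(nodes))
  out <- split(to, factor(from, levels = idx))
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(nodes)) return(NULL)
  # walk backwards inside the remaining subgraph until a node repeats
  rem <- which(indeg > 0)
  v <- rem[[1]]
  path <- v
  repeat {
    preds <- from[to == v & from %in% rem]
    v <- preds[[1]]
    if (v %in% path) {
      cyc <- path[seq(which(path == v), length(path))]
      return(nodes[rev(c(cyc, v))])
    }
    path <- c(path, v)
  }
}

#' Diseases of an identifier list covered by a DAG
#'
#' @param dag a `disease_dag`.
#' @param ids disease identifiers (association-matrix columns).
#' @return the subset of `ids` present among the DAG's nodes.
#' @export
dag_covered <- function(dag, ids) {
  stopifnot(inherits(dag, "disease_dag"))
  ids[ids %in% dag$nodes]
}

#' Construct a similarity matrix
#'
#' Square symmetric matrix of pairwise scores with an ordered identifier list.
#' Symmetry is enforced within 1e-9 and the stored matrix is exactly
#' symmetrized.
#'
#' @param values square numeric matrix.
#' @param ids identifier list matching the matrix order.
#' @return an object of class `sim_matrix`.
#' @export
similarity_matrix <- function(values, ids) {
  values <- as.matrix(values)
  ids <- trimws(as.character(ids))
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (length(ids) != nrow(values)) stop("identifier list does not match matrix size")
  if (anyDuplicated(ids)) stop("duplicate identifiers in similarity matrix")
  if (any(!is.finite(values))) stop("similarity matrix entries must be finite")
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity matrix is not symmetric (tolerance 1e-9)")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids), class = "sim_matrix")
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix: %d x %d, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Read a binary association table
#'
#' Two on-disk layouts are supported. `edge_list`: one association per row as
#' `row_id <TAB> col_id` (an optional third column is ignored); duplicate rows
#' collapse to a single 1. `dense`: a full 0/1 grid with a header row of
#' column identifiers and a first column of row identifiers.
#'
#' @param path file to read.
#' @param format `"edge_list"` or `"dense"`.
#' @return an [association_matrix()].
#' @export
read_association_table <- function(path, format = c("edge_list", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "edge_list") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             blank.lines.skip = TRUE, comment.char = "")
    if (nrow(tab) == 0) stop("empty association table")
    if (ncol(tab) < 2) stop("edge list rows need at least (row_id, col_id)")
    rid <- trimws(tab[[1]])
    cid <- trimws(tab[[2]])
    row_ids <- unique(rid)
    col_ids <- unique(cid)
    values <- matrix(0, length(row_ids), length(col_ids))
    values[cbind(match(rid, row_ids), match(cid, col_ids))] <- 1
    association_matrix(values, row_ids, col_ids)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                             check.names = FALSE, quote = "", comment.char = "")
    if (nrow(tab) == 0 || ncol(tab) == 0) stop("empty association table")
    values <- as.matrix(tab)
    if (!is.numeric(values)) stop("dense association table has non-numeric entries")
    if (any(values != 0 & values != 1)) {
      stop("dense association table has a non-binary value")
    }
    association_matrix(values, rownames(tab), colnames(tab))
  }
}

#' Write an association matrix as a TSV edge list
#'
#' @param m an `assoc_matrix`.
#' @param path output file.
#' @export
write_association_table <- function(m, path) {
  stopifnot(inherits(m, "assoc_matrix"))
  hits <- which(m$values == 1, arr.ind = TRUE)
  df <- data.frame(row = m$row_ids[hits[, 1]], col = m$col_ids[hits[, 2]])
  df <- df[order(hits[, 1], hits[, 2]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Write an association matrix as a dense TSV grid
#'
#' @param m an `assoc_matrix`.
#' @param path output file.
#' @export
write_association_dense <- function(m, path) {
  stopifnot(inherits(m, "assoc_matrix"))
  .write_grid(m$values, m$row_ids, m$col_ids, path, digits = FALSE)
}

#' Read circRNA sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the identifier.
#' Sequences are uppercased; wrapped records are concatenated; records whose
#' identifier is not in `known_ids` are excluded with a warning.
#'
#' @param path FASTA file.
#' @param known_ids circRNA identifiers of the association matrix rows.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, known_ids) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  seqs <- as.character(recs)
  names(seqs) <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1)
  sequence_set(seqs, known_ids)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a `sequence_set`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "sequence_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs$sequences)) {
    writeLines(c(paste0(">", id), seqs$sequences[[id]]), con)
  }
  invisible(NULL)
}

#' Read a disease DAG from a TSV edge list
#'
#' Rows are `parent_id <TAB> child_id`; a single-column row declares an
#' isolated node. Cycles and self-loops are rejected.
#'
#' @param path edge-list file.
#' @return a [disease_dag()].
#' @export
read_dag <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t")
  iso <- vapply(parts, function(p) sum(trimws(p) != "") == 1, logical(1))
  nodes <- vapply(parts[iso], function(p) trimws(p)[trimws(p) != ""][1], character(1))
  ed <- parts[!iso]
  edges <- if (length(ed) > 0) {
    t(vapply(ed, function(p) trimws(p)[1:2], character(2)))
  } else {
    matrix(character(0), ncol = 2)
  }
  disease_dag(edges, nodes)
}

#' Write a disease DAG edge list
#'
#' @param dag a `disease_dag`.
#' @param path output file.
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "disease_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(dag$edges) > 0) {
    writeLines(paste(dag$edges[, 1], dag$edges[, 2], sep = "\t"), con)
  }
  iso <- setdiff(dag$nodes, as.vector(dag$edges))
  if (length(iso) > 0) writeLines(iso, con)
  invisible(NULL)
}

.write_grid <- function(values, row_ids, col_ids, path, digits = TRUE) {
  fmt <- if (digits) function(v) sprintf("%.17g", v) else function(v) format(v, scientific = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", col_ids), collapse = "\t"), con)
  body <- vapply(seq_along(row_ids), function(i) {
    paste(c(row_ids[i], fmt(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(NULL)
}

#' Write a similarity matrix as a dense TSV
#'
#' Writes an id header row, an id first column, and entries at full double
#' precision (17 significant digits) so a read-back reproduces the values
#' bit-for-bit.
#'
#' @param m a `sim_matrix`.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "sim_matrix"))
  .write_grid(m$values, m$ids, m$ids, path)
}

#' Read a similarity matrix written by [write_matrix()]
#'
#' @param path dense TSV file.
#' @return a `sim_matrix`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, quote = "", comment.char = "")
  similarity_matrix(as.matrix(tab), rownames(tab))
}
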