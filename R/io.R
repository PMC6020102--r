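## File formats are plain TSV, UTF-8, with optional '#' comment lines.
## Pair lists carry no header; labelled matrix files require one.

.readTsvLines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.splitFields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1L]]

#' Read a two-column association pair list
#'
#' Each non-comment line is `<row_id>TAB<col_id>`; duplicate pairs collapse
#' to a single 1.  When `rowIds`/`colIds` are NULL the universes are
#' inferred in first-appearance order.
#'
#' @param path TSV file of id pairs (no header).
#' @param rowIds,colIds optional fixed universes; ids in the file must
#'   then resolve against them.
#' @param rowKind,colKind entity-kind labels stored on the result.
#' @return An [AssociationMatrix-class].
#' @seealso [writeAssociations()]
#' @export
readAssociations <- function(path, rowIds = NULL, colIds = NULL,
                             rowKind = "sm", colKind = "mirna") {
  tsv <- .readTsvLines(path)
  pairs <- matrix(character(), ncol = 2)
  if (length(tsv$lines)) {
    fields <- lapply(tsv$lines, .splitFields)
    bad <- which(vapply(fields, length, 1L) != 2L)
    if (length(bad))
      stop(sprintf("malformed pair at line %d of '%s': expected 2 fields",
                   tsv$lineno[bad[1L]], path))
    pairs <- do.call(rbind, fields)
  }
  if (is.null(rowIds)) rowIds <- unique(pairs[, 1L])
  if (is.null(colIds)) colIds <- unique(pairs[, 2L])
  miss <- setdiff(pairs[, 1L], rowIds)
  if (length(miss))
    stop(sprintf("row id(s) not in universe: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  miss <- setdiff(pairs[, 2L], colIds)
  if (length(miss))
    stop(sprintf("column id(s) not in universe: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  v <- matrix(0, length(rowIds), length(colIds),
              dimnames = list(rowIds, colIds))
  if (nrow(pairs)) v[pairs] <- 1
  AssociationMatrix(v, rowKind = rowKind, colKind = colKind)
}

#' Write an association matrix as a pair list
#'
#' Inverse of [readAssociations()]: emits one `<row_id>TAB<col_id>` line
#' per nonzero entry, in row-major universe order.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(assoc, path) {
  v <- asMatrix(assoc)
  idx <- which(v == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  writeLines(paste(rownames(v)[idx[, 1L]], colnames(v)[idx[, 2L]],
                   sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a labelled square similarity matrix
#'
#' Expects a header line of column ids and one row per entity
#' (`<row_id>TAB<v1>TAB...`).  The matrix is reindexed to `ids` when
#' supplied, checked for symmetry (tolerance 1e-6) and range, then
#' symmetrised as (M + t(M))/2 with the diagonal forced to 1.
#'
#' @param path TSV matrix file with header.
#' @param ids optional universe order to reindex to.
#' @param kind label stored on the result.
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, ids = NULL, kind = "similarity") {
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) stop(sprintf("empty matrix file '%s'", path))
  header <- .splitFields(tsv$lines[[1L]])
  colIds <- header[-1L]  # leading cell is a corner label (may be empty)
  rows <- lapply(tsv$lines[-1L], .splitFields)
  rowIds <- vapply(rows, `[`, "", 1L)
  v <- do.call(rbind, lapply(rows, function(f) as.numeric(f[-1L])))
  if (is.null(v) || ncol(v) != length(colIds))
    stop(sprintf("ragged matrix in '%s'", path))
  dimnames(v) <- list(rowIds, colIds)
  if (!setequal(rowIds, colIds))
    stop("matrix row and column id sets differ")
  v <- v[, rowIds, drop = FALSE]
  if (!is.null(ids)) {
    miss <- setdiff(ids, rowIds)
    if (length(miss))
      stop(sprintf("id(s) missing from matrix file: %s",
                   paste(utils::head(miss, 5), collapse = ", ")))
    v <- v[ids, ids, drop = FALSE]
  }
  SimilarityMatrix(v, kind = kind)
}

#' Write a similarity matrix in the labelled TSV dialect
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- asMatrix(sim)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], format(v[i, ], digits = 15,
                                              scientific = FALSE,
                                              trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read per-disease ancestor DAGs
#'
#' Input rows are `<disease_id>TAB<child>TAB<parent>`; all rows sharing a
#' disease id form that disease's DAG.  A disease listed in `roots` with no
#' rows yields the trivial DAG containing only the root.  Cycles in the
#' child -> parent closure are rejected.
#'
#' @param path TSV edge-list file (no header).
#' @param roots optional disease ids guaranteed a (possibly trivial) DAG.
#' @return named list of [DiseaseDAG-class] objects.
#' @export
readDiseaseDAGs <- function(path, roots = character()) {
  tsv <- .readTsvLines(path)
  edges <- matrix(character(), ncol = 3)
  if (length(tsv$lines)) {
    fields <- lapply(tsv$lines, .splitFields)
    bad <- which(vapply(fields, length, 1L) != 3L)
    if (length(bad))
      stop(sprintf("malformed DAG row at line %d of '%s': expected 3 fields",
                   tsv$lineno[bad[1L]], path))
    edges <- do.call(rbind, fields)
  }
  ids <- unique(c(edges[, 1L], roots))
  dags <- lapply(ids, function(d) {
    e <- edges[edges[, 1L] == d, -1L, drop = FALSE]
    DiseaseDAG(d, nodes = unique(c(d, c(e))), edges = e)
  })
  names(dags) <- ids
  dags
}

#' Write disease DAGs as a child/parent edge list
#'
#' @param dags named list of [DiseaseDAG-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDiseaseDAGs <- function(dags, path) {
  lines <- unlist(lapply(dags, function(dag) {
    if (!nrow(dag@edges)) return(character())
    paste(dag@disease, dag@edges[, 1L], dag@edges[, 2L], sep = "\t")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
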