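# Readers and writers for the standard formats the pipeline touches:
# mature-miRNA FASTA, association pair tables, MeSH tree-number tables,
# and labelled CSV exports.

#' Read mature miRNA sequences from FASTA
#'
#' Accepts both RNA- and DNA-style files: sequences are upper-cased and `T`
#' is canonicalized to `U` at ingest, so downstream encoders always see the
#' `{A,C,G,U}` alphabet. The record identifier is the first
#' whitespace-delimited token of the header (miRBase mature dialect).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-mir-1 demo", "acgu"), fa)
#' read_mirna_fasta(fa)
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) abort_format("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_format("malformed FASTA: ", conditionMessage(e))
  )
  if (length(set) == 0L) abort_format("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- chartr("T", "U", toupper(as.character(set)))
  bad <- regexpr("[^ACGU]", seqs)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1]
    abort_format(sprintf(
      "illegal character '%s' at position %d of record '%s'",
      substr(seqs[k], bad[k], bad[k]), bad[k], ids[k]
    ))
  }
  if (any(nchar(seqs) == 0L)) {
    abort_format("empty sequence in record '", ids[which(nchar(seqs) == 0L)[1]], "'")
  }
  if (anyDuplicated(ids)) {
    abort_format("duplicate sequence id: '", ids[duplicated(ids)][1], "'")
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Read miRNA-disease association pairs into a binary matrix
#'
#' Reads a two-column TSV (`mirna<TAB>disease`, optional header). Names are
#' matched case-insensitively after whitespace trimming; duplicate pairs
#' collapse to a single entry. Rows and columns are ordered
#' lexicographically so the matrix layout is deterministic.
#'
#' @param path Path to a TSV file of pairs.
#' @return A binary miRNA x disease matrix with dimnames; entry 1 marks a
#'   known association.
#' @export
read_association_pairs <- function(path) {
  if (!file.exists(path)) abort_format("association file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                      colClasses = "character", blank.lines.skip = TRUE),
    error = function(e) abort_format("empty or unreadable association table: ", path)
  )
  if (nrow(raw) == 0L) abort_format("association table is empty: ", path)
  if (ncol(raw) < 2L) abort_format("association table needs 2 columns (mirna, disease)")
  first <- normalize_id(unlist(raw[1, 1:2], use.names = FALSE))
  if (first[1] %in% c("mirna", "mir", "microrna") ||
      first[2] %in% c("disease", "diseases")) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) abort_format("association table has a header but no rows")
  pairs <- tibble::tibble(
    mirna = normalize_id(raw[[1]]),
    disease = normalize_id(raw[[2]])
  )
  if (any(pairs$mirna == "" | pairs$disease == "")) {
    abort_format("association table contains empty identifiers")
  }
  association_matrix(pairs)
}

#' Build an association matrix from a pair table
#'
#' @param pairs A data frame with columns `mirna` and `disease`.
#' @param mirna_ids,disease_ids Optional full id universes (so entities with
#'   no known association keep an all-zero row/column). Defaults to the ids
#'   present in `pairs`.
#' @return A binary miRNA x disease matrix, lexicographic dimnames.
#' @export
association_matrix <- function(pairs, mirna_ids = NULL, disease_ids = NULL) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  if (nrow(pairs) == 0L && (is.null(mirna_ids) || is.null(disease_ids))) {
    abort_format("no association pairs and no id universe supplied")
  }
  mids <- sort_ids(unique(c(pairs$mirna, mirna_ids)))
  dids <- sort_ids(unique(c(pairs$disease, disease_ids)))
  A <- matrix(0, length(mids), length(dids), dimnames = list(mids, dids))
  if (nrow(pairs) > 0L) A[cbind(pairs$mirna, pairs$disease)] <- 1
  A
}

#' Recover the pair table of an association matrix
#'
#' Inverse of [association_matrix()]: one row per positive entry.
#'
#' @param A Binary association matrix with dimnames.
#' @return A tibble with columns `mirna` and `disease`, lexicographic order.
#' @export
association_pairs <- function(A) {
  stopifnot(is.matrix(A))
  idx <- which(A == 1, arr.ind = TRUE)
  out <- tibble::tibble(
    mirna = rownames(A)[idx[, 1]],
    disease = colnames(A)[idx[, 2]]
  )
  dplyr::arrange(out, .data$mirna, .data$disease)
}

#' Read a disease-to-MeSH tree-number mapping as a disease DAG
#'
#' The file is a TSV with columns `disease<TAB>codes`, codes being
#' semicolon-separated dot-delimited MeSH tree numbers. The parent of code
#' `a.b.c` is `a.b`; a disease's DAG node set is the prefix closure of all
#' its codes.
#'
#' @param path Path to the TSV mapping.
#' @return A `disease_dag` object.
#' @export
read_mesh_mapping <- function(path) {
  if (!file.exists(path)) abort_format("MeSH mapping file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                      colClasses = "character", blank.lines.skip = TRUE),
    error = function(e) abort_format("empty or unreadable MeSH table: ", path)
  )
  if (nrow(raw) == 0L) abort_format("MeSH mapping table is empty: ", path)
  if (ncol(raw) < 2L) abort_format("MeSH mapping needs 2 columns (disease, codes)")
  first <- normalize_id(unlist(raw[1, 1:2], use.names = FALSE))
  if (first[1] %in% c("disease", "diseases") || first[2] %in% c("code", "codes")) {
    raw <- raw[-1, , drop = FALSE]
  }
  codes <- lapply(strsplit(raw[[2]], ";", fixed = TRUE), trimws)
  names(codes) <- normalize_id(raw[[1]])
  disease_dag(codes)
}

#' Construct a disease DAG from tree-number codes
#'
#' @param tree_numbers Named list: disease id -> character vector of
#'   dot-delimited tree-number codes.
#' @return A `disease_dag`: disease ids, their codes, the prefix-closed node
#'   set and each node's parent. Codes whose prefix names no mapped disease
#'   remain anonymous internal nodes.
#' @export
disease_dag <- function(tree_numbers) {
  stopifnot(is.list(tree_numbers), !is.null(names(tree_numbers)))
  if (length(tree_numbers) == 0L) abort_format("no diseases in MeSH mapping")
  if (anyDuplicated(names(tree_numbers))) {
    abort_format("duplicate disease in MeSH mapping: '",
                 names(tree_numbers)[duplicated(names(tree_numbers))][1], "'")
  }
  all_codes <- unlist(tree_numbers, use.names = FALSE)
  ok <- grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", all_codes)
  if (!all(ok)) abort_format("malformed tree-number code: '", all_codes[!ok][1], "'")
  if (any(lengths(tree_numbers) == 0L)) {
    abort_format("every disease needs at least one tree-number code")
  }
  nodes <- unique(unlist(lapply(all_codes, code_prefixes), use.names = FALSE))
  parent <- vapply(nodes, code_parent, character(1))
  # Cycle check (impossible under prefix truncation, asserted regardless):
  for (nd in nodes) {
    seen <- character(0)
    cur <- nd
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) rlang::abort("cycle detected in disease DAG",
                                      class = "mirgae_integrity_error")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(
    list(
      disease_ids = names(tree_numbers),
      tree_numbers = tree_numbers,
      nodes = nodes,
      parent = parent
    ),
    class = "disease_dag"
  )
}

code_prefixes <- function(code) {
  seg <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(seg), function(k) paste(seg[1:k], collapse = "."), character(1))
}

code_parent <- function(code) {
  seg <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(seg) <= 1L) NA_character_ else paste(seg[-length(seg)], collapse = ".")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d diseases, %d DAG nodes\n",
              length(x$disease_ids), length(x$nodes)))
  invisible(x)
}

#' Write a labelled matrix, ranking or metrics table to CSV
#'
#' @param x The object: a matrix with dimnames (`kind = "matrix"`), or a data
#'   frame (`kind = "ranking"` needs columns rank/mirna/disease/score and is
#'   re-sorted by descending score with ties broken by miRNA id;
#'   `kind = "metrics"` is written as-is).
#' @param path Output CSV path.
#' @param kind One of `"matrix"`, `"ranking"`, `"metrics"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, kind = c("matrix", "ranking", "metrics")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    matrix = {
      stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
      cbind(data.frame(id = rownames(x), check.names = FALSE),
            as.data.frame(x, check.names = FALSE))
    },
    ranking = {
      stopifnot(is.data.frame(x),
                all(c("rank", "mirna", "disease", "score") %in% names(x)))
      x <- x[order(-x$score, x$mirna, method = "radix"), , drop = FALSE]
      x$rank <- seq_len(nrow(x))
      x[, c("rank", "mirna", "disease", "score")]
    },
    metrics = {
      stopifnot(is.data.frame(x))
      x
    }
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rlang::abort(paste0("cannot write table to: ", path),
                        class = "mirgae_io_error")
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path)
  invisible(path)
}
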