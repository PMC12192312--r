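# File input/output: edge lists (TSV/CSV), Matrix Market biadjacency
# matrices, and the deterministic score table format.

#' Read a bipartite edge list
#'
#' Reads a two-column delimited file of (left label, right label) edges.
#' Lines starting with `#` are comments; blank lines are skipped; duplicate
#' rows collapse to one edge. Column 1 becomes the left side, column 2 the
#' right side, with first appearance fixing the index order.
#'
#' By default a label occurring in both columns is rejected, since it
#' usually signals swapped columns; set `allow_shared_labels = TRUE` to
#' accept it (sides are separate namespaces internally, so no tagging of
#' the labels themselves is needed).
#'
#' @param path Path to the file.
#' @param sep Field delimiter, `"\t"` by default (use `","` for CSV).
#' @param header Logical; if `TRUE` the first data line is discarded.
#' @param allow_shared_labels Permit the same label string on both sides.
#' @return A [bipartite_graph()].
#' @export
read_edge_list <- function(path, sep = "\t", header = FALSE,
                           allow_shared_labels = FALSE) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (length(lines) == 0L) stop(sprintf("no edges in '%s'", path))
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf != 2L
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf(
      "parse error at line %d of '%s': expected 2 fields, found %d",
      line_no[k], path, nf[k]
    ))
  }
  lft <- trimws(vapply(parts, `[[`, "", 1L))
  rgt <- trimws(vapply(parts, `[[`, "", 2L))
  blank <- !nzchar(lft) | !nzchar(rgt)
  if (any(blank)) {
    k <- which(blank)[1L]
    stop(sprintf("parse error at line %d of '%s': empty label field", line_no[k], path))
  }
  if (!allow_shared_labels) {
    shared <- intersect(unique(lft), unique(rgt))
    if (length(shared) > 0L) {
      stop(sprintf(
        "label(s) %s occur in both columns; use allow_shared_labels = TRUE if intended",
        paste(sQuote(utils::head(shared, 3L)), collapse = ", ")
      ))
    }
  }
  bipartite_graph(lft, right = rgt)
}

#' Read a biadjacency matrix in Matrix Market format
#'
#' Reads an m x n coordinate-format Matrix Market file (pattern or real;
#' every stored nonzero becomes an edge) and converts its 1-based indices
#' to a [bipartite_graph()]. Node labels default to `u<i>` / `v<j>`.
#'
#' @param path Path to the `.mtx` file.
#' @return A [bipartite_graph()].
#' @export
read_biadjacency <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  b <- methods::as(Matrix::readMM(path), "TsparseMatrix")
  if (length(b@i) == 0L) stop(sprintf("no edges in '%s'", path))
  lft <- paste0("u", b@i + 1L)
  rgt <- paste0("v", b@j + 1L)
  g <- bipartite_graph(lft, right = rgt)
  # preserve the full declared dimensions, including all-zero rows/columns
  left_all <- paste0("u", seq_len(nrow(b)))
  right_all <- paste0("v", seq_len(ncol(b)))
  new_bipartite_graph(
    left_all, right_all,
    cbind(match(g$left_labels, left_all)[g$edges[, 1L]],
          match(g$right_labels, right_all)[g$edges[, 2L]])
  )
}

#' Write a bipartite edge list
#'
#' @param graph A `bipartite_graph`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_edge_list <- function(graph, path, sep = "\t") {
  lines <- paste(
    graph$left_labels[graph$edges[, 1L]],
    graph$right_labels[graph$edges[, 2L]],
    sep = sep
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a score table deterministically
#'
#' Writes `left_label<TAB>right_label<TAB>score` rows with scores printed
#' to 10 significant digits (`%.9e`), sorted by score descending and then
#' lexicographically (byte order) by left and right label. Identical input
#' always produces byte-identical output.
#'
#' @param table A score table from [score_pairs()].
#' @param path Output path.
#' @export
write_scores <- function(table, path) {
  if (!inherits(table, "score_table")) stop("`table` must be a score_table")
  if (nrow(table) == 0L) stop("refusing to write an empty score table")
  ord <- score_order(table)
  lines <- paste(
    table$left[ord], table$right[ord],
    sprintf("%.9e", table$score[ord]),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# The package-wide deterministic ranking: score descending, then left and
# right label in C-locale (byte) order. Radix sort is stable and
# locale-independent.
score_order <- function(table) {
  order(-table$score, table$left, table$right, method = "radix")
}
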