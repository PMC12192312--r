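# Bipartite graph data model.
#
# A graph G(U, V, E) is stored as two label vectors (one per side, insertion
# order fixes the label -> index maps), a deduplicated integer edge matrix,
# and per-side adjacency lists. Sides are separate namespaces: the same label
# string may in principle occur on both sides without ambiguity because every
# operation takes (or infers) the side.

#' Construct a bipartite graph from an edge table
#'
#' Builds an undirected, unweighted bipartite network from a two-column table
#' of (left label, right label) pairs. Duplicate rows collapse to a single
#' edge; the order of first appearance fixes the label-to-index maps on each
#' side.
#'
#' @param edges A two-column `data.frame`, matrix, or pair of vectors giving
#'   the left and right endpoint labels of each edge. Coerced to character.
#' @param right Optional vector of right labels when `edges` is a vector of
#'   left labels.
#' @return An object of class `bipartite_graph`.
#' @examples
#' g <- bipartite_graph(data.frame(c("a", "a", "b"), c("x", "y", "x")))
#' n_edges(g)
#' @export
bipartite_graph <- function(edges, right = NULL) {
  if (!is.null(right)) {
    lft <- as.character(edges)
    rgt <- as.character(right)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) {
      stop("`edges` must have two columns (left label, right label)")
    }
    lft <- as.character(edges[[1L]])
    rgt <- as.character(edges[[2L]])
  }
  if (length(lft) != length(rgt)) {
    stop("left and right label vectors differ in length")
  }
  if (length(lft) == 0L) stop("no edges")
  bad <- !nzchar(lft) | !nzchar(rgt) | is.na(lft) | is.na(rgt)
  if (any(bad)) {
    stop("empty or missing label in edge row(s) ", paste(which(bad), collapse = ", "))
  }
  left_labels <- unique(lft)
  right_labels <- unique(rgt)
  e <- cbind(match(lft, left_labels), match(rgt, right_labels))
  e <- e[!duplicated(e[, 1L] * (length(right_labels) + 1L) + e[, 2L]), , drop = FALSE]
  new_bipartite_graph(left_labels, right_labels, e)
}

# Internal constructor: labels assumed unique, edges an integer k x 2 matrix
# already deduplicated and in range.
new_bipartite_graph <- function(left_labels, right_labels, edges) {
  m <- length(left_labels)
  n <- length(right_labels)
  stopifnot(m >= 1L, n >= 1L)
  storage.mode(edges) <- "integer"
  adj_left <- rep(list(integer(0)), m)
  adj_right <- rep(list(integer(0)), n)
  if (nrow(edges) > 0L) {
    sl <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(m)))
    adj_left <- lapply(sl, function(x) sort(unname(x)))
    sr <- split(edges[, 1L], factor(edges[, 2L], levels = seq_len(n)))
    adj_right <- lapply(sr, function(x) sort(unname(x)))
  }
  structure(
    list(
      left_labels = left_labels,
      right_labels = right_labels,
      edges = edges,
      adj_left = adj_left,
      adj_right = adj_right
    ),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "bipartite_graph: %d left nodes, %d right nodes, %d edges\n",
    length(x$left_labels), length(x$right_labels), nrow(x$edges)
  ))
  invisible(x)
}

#' Graph accessors
#'
#' Sizes, labels, degrees, and neighborhoods of a [bipartite_graph()].
#' `degrees()` returns the degree vector `k(.)` of one side; the two vectors
#' always satisfy `sum(degrees(g, "left")) == sum(degrees(g, "right")) ==
#' n_edges(g)`. `neighbors_of()` returns the neighbor labels `Gamma(node)` on
#' the opposite side.
#'
#' @param graph A `bipartite_graph`.
#' @param side `"left"` (the U side) or `"right"` (the V side).
#' @param node A node label (character) or 1-based index within `side`.
#' @name bigraph-accessors
NULL

#' @rdname bigraph-accessors
#' @export
n_left <- function(graph) length(graph$left_labels)

#' @rdname bigraph-accessors
#' @export
n_right <- function(graph) length(graph$right_labels)

#' @rdname bigraph-accessors
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname bigraph-accessors
#' @export
left_labels <- function(graph) graph$left_labels

#' @rdname bigraph-accessors
#' @export
right_labels <- function(graph) graph$right_labels

#' @rdname bigraph-accessors
#' @export
degrees <- function(graph, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") {
    stats::setNames(lengths(graph$adj_left), graph$left_labels)
  } else {
    stats::setNames(lengths(graph$adj_right), graph$right_labels)
  }
}

#' @rdname bigraph-accessors
#' @export
neighbors_of <- function(graph, node, side = c("left", "right")) {
  side <- match.arg(side)
  i <- resolve_node(graph, node, side)
  if (side == "left") {
    graph$right_labels[graph$adj_left[[i]]]
  } else {
    graph$left_labels[graph$adj_right[[i]]]
  }
}

# Resolve a label or index to a validated 1-based index on `side`.
resolve_node <- function(graph, node, side) {
  labs <- if (side == "left") graph$left_labels else graph$right_labels
  if (length(node) != 1L) stop("`node` must be a single label or index")
  if (is.numeric(node)) {
    i <- as.integer(node)
    if (is.na(i) || i < 1L || i > length(labs)) {
      stop(sprintf("no %s-side node with index %s", side, format(node)))
    }
    return(i)
  }
  i <- match(as.character(node), labs)
  if (is.na(i)) {
    other <- if (side == "left") graph$right_labels else graph$left_labels
    hint <- if (as.character(node) %in% other) {
      sprintf(" (it is a %s-side node)", if (side == "left") "right" else "left")
    } else {
      ""
    }
    stop(sprintf("'%s' is not a %s-side node%s", node, side, hint))
  }
  i
}

#' Biadjacency matrix
#'
#' Returns the m x n sparse 0/1 biadjacency matrix B of the network, with
#' `B[i, j] == 1` iff left node i and right node j are connected. Row and
#' column names carry the node labels.
#'
#' @param graph A `bipartite_graph`.
#' @return A sparse `Matrix::dgCMatrix`.
#' @export
biadjacency <- function(graph) {
  Matrix::sparseMatrix(
    i = graph$edges[, 1L], j = graph$edges[, 2L], x = 1,
    dims = c(n_left(graph), n_right(graph)),
    dimnames = list(graph$left_labels, graph$right_labels)
  )
}

#' @rdname bigraph-accessors
#' @param u,v Left- and right-side node labels or indices.
#' @export
has_edge <- function(graph, u, v) {
  i <- resolve_node(graph, u, "left")
  j <- resolve_node(graph, v, "right")
  any(graph$adj_left[[i]] == j)
}

#' Enumerate all unconnected cross-side pairs
#'
#' The candidate universe for link prediction: every (left, right) pair of
#' the m x n grid H that is not an edge of the graph.
#'
#' @param graph A `bipartite_graph`.
#' @return An integer matrix with columns `left` and `right` (1-based
#'   indices), ordered by left index then right index.
#' @export
all_non_edges <- function(graph) {
  m <- n_left(graph)
  n <- n_right(graph)
  key_edges <- (graph$edges[, 1L] - 1L) * n + graph$edges[, 2L]
  key_all <- seq_len(m * n)
  key <- key_all[!(key_all %in% key_edges)]
  cbind(left = (key - 1L) %/% n + 1L, right = (key - 1L) %% n + 1L)
}

# Convert a candidate specification (label or index pairs) to an integer
# index matrix, validating that every pair is a non-edge.
as_candidate_matrix <- function(graph, candidates) {
  if (is.null(candidates)) return(all_non_edges(graph))
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (ncol(candidates) < 2L) stop("`candidates` must have two columns")
  if (nrow(candidates) == 0L) {
    return(cbind(left = integer(0), right = integer(0)))
  }
  li <- if (is.numeric(candidates[[1L]])) {
    as.integer(candidates[[1L]])
  } else {
    match(as.character(candidates[[1L]]), graph$left_labels)
  }
  ri <- if (is.numeric(candidates[[2L]])) {
    as.integer(candidates[[2L]])
  } else {
    match(as.character(candidates[[2L]]), graph$right_labels)
  }
  bad <- is.na(li) | li < 1L | li > n_left(graph) |
    is.na(ri) | ri < 1L | ri > n_right(graph)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf(
      "candidate row %d (%s, %s) names an unknown node", k,
      candidates[k, 1L], candidates[k, 2L]
    ))
  }
  n <- n_right(graph)
  is_edge <- ((li - 1L) * n + ri) %in% ((graph$edges[, 1L] - 1L) * n + graph$edges[, 2L])
  if (any(is_edge)) {
    k <- which(is_edge)[1L]
    stop(sprintf(
      "candidate (%s, %s) is an existing edge",
      graph$left_labels[li[k]], graph$right_labels[ri[k]]
    ))
  }
  cbind(left = li, right = ri)
}

#' Basic topological statistics of a bipartite network
#'
#' Computes the side sizes m and n, edge count, mean degree of each side
#' (`<kU> = |E|/m`, `<kV> = |E|/n`), sparsity (the percentage of the m x n
#' pair universe that is unobserved, `100 * (1 - |E|/(m*n))`), and the
#' overall average degree `2|E|/(m+n)`. Values are exact; round only for
#' presentation.
#'
#' @param graph A `bipartite_graph` with at least one node on each side.
#' @return A `network_stats` object (a named list).
#' @examples
#' g <- toy_cn_lcl("a")
#' network_stats(g)
#' @export
network_stats <- function(graph) {
  m <- n_left(graph)
  n <- n_right(graph)
  if (m < 1L || n < 1L) stop("graph has an empty side")
  e <- n_edges(graph)
  structure(
    list(
      m = m, n = n, edge_count = e,
      mean_left_degree = e / m,
      mean_right_degree = e / n,
      sparsity_percent = 100 * (1 - e / (m * n)),
      average_degree = 2 * e / (m + n)
    ),
    class = "network_stats"
  )
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "m = %d, n = %d, |E| = %d\n",
      "<kU> = %.2f, <kV> = %.2f, sparsity = %.2f%%\n"
    ),
    x$m, x$n, x$edge_count,
    x$mean_left_degree, x$mean_right_degree, x$sparsity_percent
  ))
  invisible(x)
}

#' Split edges into a training graph and a probe set
#'
#' Draws `round(train_fraction * |E|)` edges (ties to even) uniformly at
#' random without replacement as the training set; the remainder is the
#' probe (test) set. All nodes are retained in the training graph, so nodes
#' can become isolated; they simply score zero against everything. The same
#' seed always yields the same split.
#'
#' @param graph A `bipartite_graph` with at least two edges.
#' @param train_fraction Fraction p of edges kept for training, in (0, 1).
#' @param seed Integer seed controlling the draw.
#' @return A `split_result` list with elements `train` (a
#'   `bipartite_graph`), `probe` (two-column character matrix of held-out
#'   edge labels), `probe_idx` (integer indices), `universe_size` (m*n),
#'   `train_fraction`, and `seed`.
#' @export
split_edges <- function(graph, train_fraction = 0.9, seed) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1")
  }
  e <- n_edges(graph)
  if (e < 2L) stop("graph must have at least 2 edges to split")
  n_train <- round(train_fraction * e)
  if (n_train < 1L || n_train >= e) {
    stop(sprintf(
      "degenerate split: round(%g * %d) = %d training edges", train_fraction, e, n_train
    ))
  }
  probe_rows <- with_seed(seed, sort(sample.int(e, e - n_train)))
  train <- new_bipartite_graph(
    graph$left_labels, graph$right_labels,
    graph$edges[-probe_rows, , drop = FALSE]
  )
  probe_idx <- graph$edges[probe_rows, , drop = FALSE]
  probe <- cbind(
    left = graph$left_labels[probe_idx[, 1L]],
    right = graph$right_labels[probe_idx[, 2L]]
  )
  structure(
    list(
      train = train,
      probe = probe,
      probe_idx = probe_idx,
      universe_size = n_left(graph) * n_right(graph),
      train_fraction = train_fraction,
      seed = as.integer(seed)
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "split_result: %d training edges, %d probe edges (p = %g, seed = %d)\n",
    n_edges(x$train), nrow(x$probe), x$train_fraction, x$seed
  ))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
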