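# The core similarity index: quadrangle-graph extraction and the
# STRA / QDRA / QSRA components of the NeiBLP score.
#
# For an unconnected pair (u, v) with u on the left and v on the right, the
# shortest possible route between them is a length-three (L3) path
# u - s - t - v with s a right-side and t a left-side intermediate. The
# quadrangle graph Q_uv collects every such path; closing any one of them
# with the edge (u, v) would complete a quadrangle, the bipartite analogue
# of triadic closure.

#' Extract the quadrangle graph of a candidate pair
#'
#' Enumerates the set `P_uv` of distinct L3 paths `u - s - t - v` between a
#' left node `u` and a right node `v` that are not connected, together with
#' the node set of the induced quadrangle graph `Q_uv`. Each path is
#' identified by its intermediate pair `(s, t)`; paths are listed once, in
#' order of s-index then t-index.
#'
#' @param graph A training `bipartite_graph`.
#' @param u Left-side node label or index.
#' @param v Right-side node label or index.
#' @return A `quadrangle_graph` list with elements `u`, `v` (labels),
#'   `paths` (data frame with character columns `s`, `t`), `s_nodes`,
#'   `t_nodes` (distinct intermediates), and `nodes` (all labels of Q_uv,
#'   side-tagged only in the sense of being split into `left` and `right`).
#' @examples
#' g <- bipartite_graph(data.frame(c("u", "t", "t"), c("s", "s", "v")))
#' enumerate_l3(g, "u", "v")$paths
#' @export
enumerate_l3 <- function(graph, u, v) {
  i <- resolve_node(graph, u, "left")
  j <- resolve_node(graph, v, "right")
  if (any(graph$adj_left[[i]] == j)) {
    stop(sprintf(
      "(%s, %s) is not a candidate pair: the edge already exists",
      graph$left_labels[i], graph$right_labels[j]
    ))
  }
  s_idx <- graph$adj_left[[i]]          # right-side neighbors of u
  vs <- graph$adj_right[[j]]            # left-side neighbors of v
  ps <- integer(0)
  pt <- integer(0)
  for (s in s_idx) {
    t_hits <- intersect(graph$adj_right[[s]], vs)
    if (length(t_hits) > 0L) {
      ps <- c(ps, rep.int(s, length(t_hits)))
      pt <- c(pt, sort(t_hits))
    }
  }
  structure(
    list(
      u = graph$left_labels[i],
      v = graph$right_labels[j],
      paths = data.frame(
        s = graph$right_labels[ps],
        t = graph$left_labels[pt],
        stringsAsFactors = FALSE
      ),
      s_idx = ps, t_idx = pt,
      s_nodes = graph$right_labels[unique(ps)],
      t_nodes = graph$left_labels[unique(pt)],
      nodes = list(
        left = c(graph$left_labels[i], graph$left_labels[sort(unique(pt))]),
        right = c(graph$right_labels[j], graph$right_labels[sort(unique(ps))])
      )
    ),
    class = "quadrangle_graph"
  )
}

#' @export
print.quadrangle_graph <- function(x, ...) {
  cat(sprintf(
    "quadrangle_graph for (%s, %s): %d L3 path(s), %d node(s)\n",
    x$u, x$v, nrow(x$paths),
    length(x$nodes$left) + length(x$nodes$right)
  ))
  invisible(x)
}

#' Same-type resource allocation between two same-side nodes
#'
#' The STRA score of two nodes `a` and `b` on the same side is
#' `sum(1 / k_x)` over their shared opposite-side neighbors
#' `x` in `Gamma(a) & Gamma(b)`, with degrees taken in the full training
#' graph. Nodes sharing low-degree neighbors are considered more alike.
#'
#' @param graph A training `bipartite_graph`.
#' @param a,b Node labels or indices, both on `side`.
#' @param side Which side `a` and `b` live on.
#' @return A non-negative number; 0 when the neighborhoods are disjoint.
#' @export
stra <- function(graph, a, b, side = c("left", "right")) {
  side <- match.arg(side)
  ia <- resolve_node(graph, a, side)
  ib <- resolve_node(graph, b, side)
  if (ia == ib) stop("`a` and `b` must be distinct nodes")
  if (side == "left") {
    shared <- intersect(graph$adj_left[[ia]], graph$adj_left[[ib]])
    k <- lengths(graph$adj_right)
  } else {
    shared <- intersect(graph$adj_right[[ia]], graph$adj_right[[ib]])
    k <- lengths(graph$adj_left)
  }
  if (length(shared) == 0L) return(0)
  sum(1 / k[shared])
}

#' Quadrangle-graph similarity components
#'
#' `qdra()` is the cross-type component: a degree-normalized resource
#' allocation over the distinct L3 paths of `Q_uv`,
#' `sum over (s, t) in P_uv of (1/k_s)(1/k_t)`.
#' `qsra()` is the same-type component: with `T` the distinct left and `S`
#' the distinct right intermediates of `P_uv`, it is the product
#' `[sum over t in T of STRA(u, t)] * [sum over s in S of STRA(v, s)]`,
#' all neighbor sets and degrees taken in the full training graph.
#' `neiblp_score()` is their parameter-free sum; it rewards candidate pairs
#' whose quadrangle graphs are rich in low-degree intermediates.
#'
#' @inheritParams enumerate_l3
#' @return A non-negative, finite number; 0 when `P_uv` is empty.
#' @examples
#' g <- toy_quadrangle()
#' qdra(g, "u", "v")    # 1/12
#' qsra(g, "u", "v")    # 7/12
#' neiblp_score(g, "u", "v")
#' @export
qdra <- function(graph, u, v) {
  q <- enumerate_l3(graph, u, v)
  if (length(q$s_idx) == 0L) return(0)
  ku <- lengths(graph$adj_left)
  kv <- lengths(graph$adj_right)
  sum(1 / (kv[q$s_idx] * ku[q$t_idx]))
}

#' @rdname qdra
#' @export
qsra <- function(graph, u, v) {
  q <- enumerate_l3(graph, u, v)
  if (length(q$s_idx) == 0L) return(0)
  i <- resolve_node(graph, u, "left")
  j <- resolve_node(graph, v, "right")
  ku <- lengths(graph$adj_left)
  kv <- lengths(graph$adj_right)
  left_factor <- 0
  for (t in unique(q$t_idx)) {
    x <- intersect(graph$adj_left[[i]], graph$adj_left[[t]])
    if (length(x) > 0L) left_factor <- left_factor + sum(1 / kv[x])
  }
  right_factor <- 0
  for (s in unique(q$s_idx)) {
    y <- intersect(graph$adj_right[[j]], graph$adj_right[[s]])
    if (length(y) > 0L) right_factor <- right_factor + sum(1 / ku[y])
  }
  left_factor * right_factor
}

#' @rdname qdra
#' @export
neiblp_score <- function(graph, u, v) {
  qdra(graph, u, v) + qsra(graph, u, v)
}
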