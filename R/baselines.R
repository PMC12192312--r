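# Baseline similarity indices for bipartite link prediction.
#
# Neighborhood indices (CN, JC, AA, RA) use the quadratic-closure notion of
# common neighbors: because a left and a right node can never share a direct
# neighbor, the common-neighbor set of (u, v) is
#   CN(u, v) = (Gamma(u) & hat(Gamma)(v)) | (hat(Gamma)(u) & Gamma(v)),
# where hat(Gamma)(a) is the same-side two-hop neighborhood of a. Every
# member of CN(u, v) lies on an L3 path between u and v and therefore has
# degree >= 2. Local-community indices (LCL, CAR, CAA, CRA) additionally
# count the edges running between the two neighborhoods. Path indices count
# (or weight) length-3 and longer odd-length walks via powers of the
# adjacency matrix. Projection indices propagate resources across the
# bipartite structure in two mass-conserving steps.

#' Hyperparameters for the configurable indices
#'
#' @param beta Path-damping weight. Used by `lp35` (default 0.1) and `lpop`
#'   (default `1 / lambda_max`, the reciprocal of the largest singular value
#'   of the training biadjacency). Ignored by other methods.
#' @param max_odd_length Odd truncation order for `lpop`'s series (default
#'   21). `Inf` requests the closed form, which requires
#'   `beta * lambda_max < 1`.
#' @param l3_norm Normalization of the `l3` index: `"intermediate"`
#'   (default) divides each path by `sqrt(k_s * k_t)`, the degrees of its
#'   two intermediate nodes; `"endpoint"` divides the raw path count by
#'   `|Gamma(u)| * |Gamma(v)|`.
#' @return A `method_config` list.
#' @export
method_config <- function(beta = NULL, max_odd_length = 21,
                          l3_norm = c("intermediate", "endpoint")) {
  l3_norm <- match.arg(l3_norm)
  if (!is.null(beta) && (!is.numeric(beta) || beta <= 0)) {
    stop("`beta` must be a positive number")
  }
  if (!identical(max_odd_length, Inf)) {
    max_odd_length <- as.integer(max_odd_length)
    if (is.na(max_odd_length) || max_odd_length < 3L || max_odd_length %% 2L == 0L) {
      stop("`max_odd_length` must be an odd integer >= 3 (or Inf)")
    }
  }
  structure(
    list(beta = beta, max_odd_length = max_odd_length, l3_norm = l3_norm),
    class = "method_config"
  )
}

# Common-neighbor machinery ---------------------------------------------

# Same-side two-hop neighborhood hat(Gamma) of one node, as indices.
two_hop <- function(graph, i, side) {
  if (side == "left") {
    unique(unlist(graph$adj_right[graph$adj_left[[i]]], use.names = FALSE))
  } else {
    unique(unlist(graph$adj_left[graph$adj_right[[i]]], use.names = FALSE))
  }
}

# Members of CN(u, v) for a candidate pair, split by side (indices).
cn_members <- function(graph, i, j) {
  list(
    right = intersect(graph$adj_left[[i]], two_hop(graph, j, "right")),
    left = intersect(two_hop(graph, i, "left"), graph$adj_right[[j]])
  )
}

check_candidate <- function(graph, u, v) {
  i <- resolve_node(graph, u, "left")
  j <- resolve_node(graph, v, "right")
  if (any(graph$adj_left[[i]] == j)) {
    stop(sprintf(
      "(%s, %s) is not a candidate pair: the edge already exists",
      graph$left_labels[i], graph$right_labels[j]
    ))
  }
  c(i = i, j = j)
}

#' Neighborhood-based baseline scores
#'
#' Scores one candidate pair with a classical common-neighbor index adapted
#' to bipartite networks: `cn` is `|CN(u, v)|`; `jc` divides it by
#' `|Gamma(u) | Gamma(v)|` (which equals `k_u + k_v` since the two
#' neighborhoods live on opposite sides); `aa` sums `1 / log2(k_z)` and
#' `ra` sums `1 / k_z` over the members `z` of `CN(u, v)`.
#'
#' @inheritParams enumerate_l3
#' @param method One of `"cn"`, `"jc"`, `"aa"`, `"ra"`.
#' @return A non-negative number; 0 when `CN(u, v)` is empty.
#' @export
neighborhood_score <- function(graph, u, v, method = c("cn", "jc", "aa", "ra")) {
  method <- match.arg(method)
  ij <- check_candidate(graph, u, v)
  mem <- cn_members(graph, ij[["i"]], ij[["j"]])
  kz <- c(lengths(graph$adj_right)[mem$right], lengths(graph$adj_left)[mem$left])
  switch(method,
    cn = length(kz),
    jc = {
      denom <- length(graph$adj_left[[ij[["i"]]]]) + length(graph$adj_right[[ij[["j"]]]])
      if (length(kz) == 0L) 0 else length(kz) / denom
    },
    aa = if (length(kz) == 0L) 0 else sum(1 / log2(kz)),
    ra = if (length(kz) == 0L) 0 else sum(1 / kz)
  )
}

#' Local-community baseline scores
#'
#' The local community links of a candidate pair are the edges `(s, t)` with
#' `s` a neighbor of `u` and `t` a neighbor of `v`; `lcl` counts them.
#' `car` multiplies the CN count by the LCL count, so it vanishes whenever
#' the two neighborhoods are not interlinked even if common neighbors
#' abound. `caa` and `cra` weight each member `z` of `CN(u, v)` by its
#' local-community degree `gamma(z)` (the number of LCL edges incident to
#' `z`) over `log2(k_z)` and `k_z` respectively.
#'
#' @inheritParams enumerate_l3
#' @param method One of `"lcl"`, `"car"`, `"caa"`, `"cra"`.
#' @return A non-negative number.
#' @export
lcp_score <- function(graph, u, v, method = c("lcl", "car", "caa", "cra")) {
  method <- match.arg(method)
  ij <- check_candidate(graph, u, v)
  i <- ij[["i"]]
  j <- ij[["j"]]
  gu <- graph$adj_left[[i]]   # right-side neighbors of u
  gv <- graph$adj_right[[j]]  # left-side neighbors of v
  # gamma(z) per side: number of LCL edges incident to each member
  gamma_right <- vapply(gu, function(s) {
    length(intersect(graph$adj_right[[s]], gv))
  }, integer(1))
  lcl <- sum(gamma_right)
  if (method == "lcl") return(lcl)
  if (method == "car") {
    return(neighborhood_score(graph, u, v, "cn") * lcl)
  }
  mem <- cn_members(graph, i, j)
  g_r <- gamma_right[match(mem$right, gu)]
  g_l <- vapply(mem$left, function(t) {
    length(intersect(graph$adj_left[[t]], gu))
  }, integer(1))
  kz <- c(lengths(graph$adj_right)[mem$right], lengths(graph$adj_left)[mem$left])
  gz <- c(g_r, g_l)
  if (length(kz) == 0L) return(0)
  switch(method,
    caa = sum(gz / log2(kz)),
    cra = sum(gz / kz)
  )
}

#' Path-based baseline scores
#'
#' `lp3` counts length-3 paths (the `(u, v)` entry of the cubed full
#' adjacency matrix); `lp35` adds `beta` times the length-5 walk count;
#' `lpop` sums `beta^l` times the length-`l` walk count over odd `l` up to
#' `max_odd_length` (the length-1 term is zero on candidate non-edges);
#' `l3` is the degree-normalized path count controlled by
#' `config$l3_norm`.
#'
#' @inheritParams enumerate_l3
#' @param method One of `"l3"`, `"lp3"`, `"lp35"`, `"lpop"`.
#' @param config A [method_config()].
#' @return A non-negative number.
#' @export
path_score <- function(graph, u, v, method = c("l3", "lp3", "lp35", "lpop"),
                       config = method_config()) {
  method <- match.arg(method)
  ij <- check_candidate(graph, u, v)
  s <- score_matrix(graph, method, config)
  s[ij[["i"]], ij[["j"]]]
}

#' Projection-based baseline scores
#'
#' Two-step mass-conserving resource allocation. For `nbi`, one unit of
#' resource sits on each right-side neighbor of `u`; every right node
#' spreads its resource equally over its `k` neighbors, then every left
#' node spreads what it received equally over its neighbors; the score is
#' the mass arriving at `v`. `bpr` runs the mirrored process from `v`'s
#' left-side neighborhood towards `u`. Both reduce to entries of
#' degree-weighted triple products of the biadjacency matrix, and for
#' undirected, unweighted networks the two directions give identical
#' scores (the normalizations always land on the two intermediate nodes).
#'
#' @inheritParams enumerate_l3
#' @param method `"nbi"` or `"bpr"`.
#' @return A non-negative number; 0 when `u` or `v` is isolated.
#' @export
projection_score <- function(graph, u, v, method = c("nbi", "bpr")) {
  method <- match.arg(method)
  ij <- check_candidate(graph, u, v)
  s <- score_matrix(graph, method, method_config())
  s[ij[["i"]], ij[["j"]]]
}
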