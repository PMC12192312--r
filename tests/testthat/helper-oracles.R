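# Independent brute-force oracles. Everything here works on a plain dense
# 0/1 matrix rebuilt from the graph's edge list with base R only, so the
# checks do not share code paths with the package implementations.

o_dense <- function(g) {
  B <- matrix(0, n_left(g), n_right(g))
  B[g$edges] <- 1
  B
}

# Random bipartite graph with at least one edge, labels a1.., b1..
rand_bigraph <- function(m, n, p = 0.3) {
  repeat {
    hits <- which(matrix(runif(m * n) < p, m, n), arr.ind = TRUE)
    if (nrow(hits) >= 1) break
  }
  bipartite_graph(paste0("a", hits[, 1]), right = paste0("b", hits[, 2]))
}

# Full (m+n) x (m+n) symmetric adjacency; left nodes first.
o_full_adj <- function(B) {
  m <- nrow(B); n <- ncol(B)
  A <- matrix(0, m + n, m + n)
  A[seq_len(m), m + seq_len(n)] <- B
  A[m + seq_len(n), seq_len(m)] <- t(B)
  A
}

# Entry (u, v) of the l-th power of the full adjacency (walk count).
o_walks <- function(B, i, j, l) {
  A <- o_full_adj(B)
  P <- A
  for (k in seq_len(l - 1)) P <- P %*% A
  P[i, nrow(B) + j]
}

# Distinct L3 paths (s, t) between left i and right j, by triple loop.
o_paths3 <- function(B, i, j) {
  out <- NULL
  for (s in seq_len(ncol(B))) {
    for (t in seq_len(nrow(B))) {
      if (B[i, s] == 1 && B[t, s] == 1 && B[t, j] == 1) out <- rbind(out, c(s, t))
    }
  }
  out
}

o_stra <- function(B, ia, ib, side) {
  if (side == "left") {
    shared <- which(B[ia, ] == 1 & B[ib, ] == 1)
    if (length(shared) == 0) return(0)
    sum(1 / colSums(B)[shared])
  } else {
    shared <- which(B[, ia] == 1 & B[, ib] == 1)
    if (length(shared) == 0) return(0)
    sum(1 / rowSums(B)[shared])
  }
}

o_qdra <- function(B, i, j) {
  P <- o_paths3(B, i, j)
  if (is.null(P)) return(0)
  sum(1 / (colSums(B)[P[, 1]] * rowSums(B)[P[, 2]]))
}

o_qsra <- function(B, i, j) {
  P <- o_paths3(B, i, j)
  if (is.null(P)) return(0)
  kv <- colSums(B); ku <- rowSums(B)
  lf <- 0
  for (t in unique(P[, 2])) {
    x <- which(B[i, ] == 1 & B[t, ] == 1)
    if (length(x) > 0) lf <- lf + sum(1 / kv[x])
  }
  rf <- 0
  for (s in unique(P[, 1])) {
    y <- which(B[, j] == 1 & B[, s] == 1)
    if (length(y) > 0) rf <- rf + sum(1 / ku[y])
  }
  lf * rf
}

# Dense matrix form of the cross-type component.
o_qdra_matrix <- function(B) {
  ku <- rowSums(B); kv <- colSums(B)
  iku <- ifelse(ku > 0, 1 / ku, 0); ikv <- ifelse(kv > 0, 1 / kv, 0)
  B %*% diag(ikv, ncol(B)) %*% t(B) %*% diag(iku, nrow(B)) %*% B
}

# Common-neighbor set of candidate (i, j): right members then left members.
o_cn_members <- function(B, i, j) {
  m <- nrow(B); n <- ncol(B)
  hat_v <- unique(unlist(lapply(which(B[, j] == 1), function(t) which(B[t, ] == 1))))
  hat_u <- unique(unlist(lapply(which(B[i, ] == 1), function(s) which(B[, s] == 1))))
  list(
    right = intersect(which(B[i, ] == 1), hat_v),
    left = intersect(hat_u, which(B[, j] == 1))
  )
}

o_lcl <- function(B, i, j) {
  cnt <- 0
  for (s in which(B[i, ] == 1)) {
    for (t in which(B[, j] == 1)) cnt <- cnt + B[t, s]
  }
  cnt
}

# Explicit two-step mass-conserving resource spreading from u's right-side
# neighborhood towards v.
o_nbi <- function(B, i, j) {
  ku <- rowSums(B); kv <- colSums(B)
  res_right <- B[i, ]                                  # unit per neighbor of u
  res_left <- rep(0, nrow(B))
  for (s in which(res_right > 0)) {
    for (t in which(B[, s] == 1)) res_left[t] <- res_left[t] + res_right[s] / kv[s]
  }
  out <- 0
  for (t in which(res_left > 0)) {
    if (B[t, j] == 1) out <- out + res_left[t] / ku[t]
  }
  out
}

o_auc <- function(pos, neg) {
  wins <- ties <- 0
  for (a in pos) {
    for (b in neg) {
      if (a > b) wins <- wins + 1 else if (a == b) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Exhaustive ranking with the package's documented tie rule.
o_precision <- function(tab, probe_keys, L) {
  ord <- order(-tab$score, tab$left, tab$right, method = "radix")
  top <- paste(tab$left[ord[seq_len(L)]], tab$right[ord[seq_len(L)]], sep = "\r")
  sum(top %in% probe_keys) / L
}

path_graph <- function() {
  # u - s - t - v chain
  bipartite_graph(data.frame(c("u", "t", "t"), c("s", "s", "v")))
}
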