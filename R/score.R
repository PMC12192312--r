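# Whole-matrix scoring: every registered index is expressible through
# sparse products of the training biadjacency B with degree-derived
# diagonal weights, so the m x n score matrix for all pairs at once is a
# handful of Matrix operations. Per-pair formulas (qdra, qsra, the
# baseline *_score functions) define correctness; the matrix routes are
# optimizations whose agreement with them is enforced by tests.

METHOD_IDS <- c(
  "neiblp", "qdra", "qsra",
  "cn", "jc", "aa", "ra",
  "lcl", "car", "caa", "cra",
  "l3", "lp3", "lp35", "lpop",
  "nbi", "bpr"
)

#' Registered method identifiers
#'
#' @return Character vector of the method ids accepted by [score_pairs()],
#'   [run_experiment()] and the command-line interface.
#' @export
available_methods <- function() METHOD_IDS

# Largest singular value of B by power iteration on t(B) %*% B. The
# iterate starts from the uniform vector, which always overlaps the
# nonnegative leading eigenvector.
lambda_max <- function(B) {
  M <- Matrix::crossprod(B)
  x <- rep(1 / sqrt(ncol(B)), ncol(B))
  lam <- 0
  for (it in seq_len(500L)) {
    y <- as.numeric(M %*% x)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(0)
    y <- y / nrm
    if (it > 1L && abs(nrm - lam) <= 1e-12 * max(1, lam)) {
      lam <- nrm
      break
    }
    lam <- nrm
    x <- y
  }
  sqrt(lam)
}

# Dense m x n matrix of scores for all pairs under one method. Entries at
# positions corresponding to existing edges are not meaningful; callers
# only read non-edge positions.
score_matrix <- function(graph, method, config = method_config()) {
  if (!(method %in% METHOD_IDS)) {
    stop(sprintf(
      "unknown method '%s'; available methods: %s",
      method, paste(METHOD_IDS, collapse = ", ")
    ))
  }
  B <- biadjacency(graph)
  ku <- Matrix::rowSums(B)
  kv <- Matrix::colSums(B)
  inv <- function(k) ifelse(k > 0, 1 / k, 0)
  loginv <- function(k) ifelse(k >= 2, 1 / log2(k), 0)
  DUi <- Matrix::Diagonal(x = inv(ku))
  DVi <- Matrix::Diagonal(x = inv(kv))

  s <- switch(method,
    qdra = B %*% DVi %*% Matrix::t(B) %*% DUi %*% B,
    qsra = qsra_matrix(B, DUi, DVi),
    neiblp = B %*% DVi %*% Matrix::t(B) %*% DUi %*% B + qsra_matrix(B, DUi, DVi),
    cn = {
      R2 <- 1 * (Matrix::crossprod(B) > 0)
      L2 <- 1 * (Matrix::tcrossprod(B) > 0)
      B %*% R2 + L2 %*% B
    },
    jc = {
      R2 <- 1 * (Matrix::crossprod(B) > 0)
      L2 <- 1 * (Matrix::tcrossprod(B) > 0)
      cnm <- as.matrix(B %*% R2 + L2 %*% B)
      denom <- outer(ku, kv, `+`)
      out <- ifelse(cnm > 0, cnm / denom, 0)
      out
    },
    aa = {
      R2 <- 1 * (Matrix::crossprod(B) > 0)
      L2 <- 1 * (Matrix::tcrossprod(B) > 0)
      B %*% Matrix::Diagonal(x = loginv(kv)) %*% R2 +
        L2 %*% Matrix::Diagonal(x = loginv(ku)) %*% B
    },
    ra = {
      R2 <- 1 * (Matrix::crossprod(B) > 0)
      L2 <- 1 * (Matrix::tcrossprod(B) > 0)
      B %*% DVi %*% R2 + L2 %*% DUi %*% B
    },
    lcl = Matrix::tcrossprod(B) %*% B,
    car = {
      R2 <- 1 * (Matrix::crossprod(B) > 0)
      L2 <- 1 * (Matrix::tcrossprod(B) > 0)
      as.matrix(B %*% R2 + L2 %*% B) * as.matrix(Matrix::tcrossprod(B) %*% B)
    },
    caa = {
      R2 <- Matrix::crossprod(B)
      L2 <- Matrix::tcrossprod(B)
      B %*% Matrix::Diagonal(x = loginv(kv)) %*% R2 +
        L2 %*% Matrix::Diagonal(x = loginv(ku)) %*% B
    },
    cra = {
      R2 <- Matrix::crossprod(B)
      L2 <- Matrix::tcrossprod(B)
      B %*% DVi %*% R2 + L2 %*% DUi %*% B
    },
    l3 = {
      if (config$l3_norm == "intermediate") {
        DVh <- Matrix::Diagonal(x = sqrt(inv(kv)))
        DUh <- Matrix::Diagonal(x = sqrt(inv(ku)))
        B %*% DVh %*% Matrix::t(B) %*% DUh %*% B
      } else {
        raw <- as.matrix(Matrix::tcrossprod(B) %*% B)
        ifelse(raw > 0, raw / outer(ku, kv), 0)
      }
    },
    lp3 = Matrix::tcrossprod(B) %*% B,
    lp35 = {
      beta <- if (is.null(config$beta)) 0.1 else config$beta
      L2 <- Matrix::tcrossprod(B)
      L2 %*% B + beta * (L2 %*% L2 %*% B)
    },
    lpop = lpop_matrix(B, config),
    nbi = B %*% DVi %*% Matrix::t(B) %*% DUi %*% B,
    bpr = {
      # mirrored spreading, composed from the transposed network
      Bt <- Matrix::t(B)
      Matrix::t(Bt %*% DUi %*% B %*% DVi %*% Bt)
    }
  )
  out <- as.matrix(s)
  dimnames(out) <- list(graph$left_labels, graph$right_labels)
  out
}

# Same-type component for all pairs: on candidate non-edges the distinct-
# intermediate sums of the per-pair definition reduce to
#   (sum over paths of 1/k_s) * (sum over paths of 1/k_t),
# because for any left intermediate t of P_uv the common neighbors of u and
# t are exactly the right partners of t in P_uv (an extra common neighbor
# would itself complete an L3 path). Hence the Hadamard product below.
qsra_matrix <- function(B, DUi, DVi) {
  left_factor <- B %*% DVi %*% Matrix::t(B) %*% B
  right_factor <- B %*% Matrix::t(B) %*% DUi %*% B
  as.matrix(left_factor) * as.matrix(right_factor)
}

# Odd-length damped walk series beta*B + beta^3*B^3 + beta^5*B^5 + ...
lpop_matrix <- function(B, config) {
  lmax <- lambda_max(B)
  beta <- if (is.null(config$beta)) {
    if (lmax == 0) stop("graph has no edges; lambda_max is zero")
    1 / lmax
  } else {
    config$beta
  }
  if (identical(config$max_odd_length, Inf)) {
    if (beta * lmax >= 1) {
      stop(sprintf(
        paste0(
          "the odd-path series diverges for beta * lambda_max = %.4f >= 1; ",
          "request a finite truncation via max_odd_length"
        ),
        beta * lmax
      ))
    }
    n <- ncol(B)
    inner <- solve(Matrix::Diagonal(n) - beta^2 * Matrix::crossprod(B))
    return(beta * B %*% inner)
  }
  L2 <- Matrix::tcrossprod(B)
  acc <- beta * B
  pw <- B
  for (l in seq(3L, config$max_odd_length, by = 2L)) {
    pw <- L2 %*% pw
    acc <- acc + beta^l * pw
  }
  acc
}

#' Score a set of candidate pairs under one method
#'
#' Computes similarity scores for candidate (left, right) pairs that are
#' not edges of the training graph. With `candidates = NULL` the whole
#' candidate universe (every non-edge of the m x n grid) is scored. The
#' result is independent of the candidate enumeration order: rows are
#' returned in the package-wide deterministic ranking (score descending,
#' then left and right label in byte order).
#'
#' @param graph The training `bipartite_graph`.
#' @param method A method id from [available_methods()].
#' @param candidates Optional two-column table of labels (or indices) of
#'   the pairs to score; every pair must be a non-edge.
#' @param config A [method_config()] supplying hyperparameters.
#' @return A `score_table`: a data frame with columns `left`, `right`,
#'   `score`, carrying the method id, config, and training graph as
#'   attributes.
#' @examples
#' g <- toy_quadrangle()
#' head(score_pairs(g, "neiblp"), 3)
#' @export
score_pairs <- function(graph, method, candidates = NULL,
                        config = method_config()) {
  if (!(method %in% METHOD_IDS)) {
    stop(sprintf(
      "unknown method '%s'; available methods: %s",
      method, paste(METHOD_IDS, collapse = ", ")
    ))
  }
  cand <- as_candidate_matrix(graph, candidates)
  if (nrow(cand) == 0L) {
    tab <- data.frame(
      left = character(0), right = character(0), score = numeric(0),
      stringsAsFactors = FALSE
    )
    return(as_score_table(tab, method, graph, config))
  }
  s <- score_matrix(graph, method, config)
  tab <- data.frame(
    left = graph$left_labels[cand[, 1L]],
    right = graph$right_labels[cand[, 2L]],
    score = s[cand],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$score, tab$left, tab$right, method = "radix"), ]
  rownames(tab) <- NULL
  as_score_table(tab, method, graph, config)
}

as_score_table <- function(tab, method, graph, config) {
  structure(
    tab,
    method = method,
    graph = graph,
    config = config,
    class = c("score_table", "data.frame")
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "score_table: method '%s', %d candidate pair(s)\n",
    attr(x, "method"), nrow(x)
  ))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 10L), ...)
    if (nrow(x) > 10L) cat(sprintf("... %d more row(s)\n", nrow(x) - 10L))
  }
  invisible(x)
}
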