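# Synthetic bipartite network generators.
#
# Two models cover the regimes the scorers must face: a configuration
# model with discrete power-law degree sequences emulates the heavy-tailed
# degree heterogeneity of real interaction networks (few hubs, many
# low-degree nodes), and a planted-block model provides ground-truth
# community structure on which link prediction is genuinely learnable.

#' Specification for a synthetic bipartite network
#'
#' @param model `"configuration"` (heavy-tailed degree sequences wired at
#'   random) or `"planted_block"` (independent edge coin flips with a
#'   higher probability inside matched left/right blocks).
#' @param m,n Side sizes.
#' @param exponent Power-law exponent of the degree distribution
#'   (configuration model), > 1. One value for both sides or a length-2
#'   vector `(left, right)`.
#' @param mean_degree Target mean left degree; the number of edges is
#'   `round(mean_degree * m)`. Ignored when `target_edges` is given.
#' @param target_edges Exact number of edges to aim for.
#' @param min_degree Minimum degree(s) of the power-law sampler; when
#'   `NULL`, the smallest value whose truncated power-law mean best
#'   matches the requested mean degree is used per side.
#' @param blocks Number of planted blocks (planted-block model).
#' @param p_within,p_between Edge probabilities inside and outside the
#'   matched blocks.
#' @return A `generator_spec` list, validated.
#' @export
generator_spec <- function(model = c("configuration", "planted_block"),
                           m = 500, n = 500,
                           exponent = 2.5, mean_degree = 8,
                           target_edges = NULL, min_degree = NULL,
                           blocks = 4, p_within = 0.5, p_between = 0.02) {
  model <- match.arg(model)
  m <- as.integer(m)
  n <- as.integer(n)
  if (m < 1L || n < 1L) stop("side sizes must be positive")
  if (model == "configuration") {
    exponent <- rep_len(as.numeric(exponent), 2L)
    if (any(exponent <= 1)) stop("power-law exponent must exceed 1")
    if (is.null(target_edges)) {
      if (is.null(mean_degree) || mean_degree <= 0) {
        stop("supply `mean_degree` > 0 or `target_edges`")
      }
      target_edges <- round(mean_degree * m)
    }
    target_edges <- as.integer(target_edges)
    if (target_edges < 1L || target_edges > m * n) {
      stop(sprintf("infeasible target of %d edges for a %d x %d grid", target_edges, m, n))
    }
    if (!is.null(min_degree)) {
      min_degree <- rep_len(as.integer(min_degree), 2L)
      if (any(min_degree < 1L)) stop("`min_degree` must be >= 1")
      if (min_degree[1L] > n || min_degree[2L] > m) {
        stop("infeasible spec: minimum degree exceeds the opposite side size")
      }
    }
  } else {
    blocks <- as.integer(blocks)
    if (blocks < 1L || blocks > min(m, n)) stop("`blocks` must be in 1..min(m, n)")
    if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1) {
      stop("block probabilities must lie in [0, 1]")
    }
  }
  structure(
    list(
      model = model, m = m, n = n,
      exponent = if (model == "configuration") exponent else NULL,
      target_edges = if (model == "configuration") target_edges else NULL,
      min_degree = if (model == "configuration") min_degree else NULL,
      blocks = if (model == "planted_block") blocks else NULL,
      p_within = if (model == "planted_block") p_within else NULL,
      p_between = if (model == "planted_block") p_between else NULL
    ),
    class = "generator_spec"
  )
}

#' Generate a synthetic bipartite network
#'
#' Draws a network from a [generator_spec()]. The configuration model
#' samples per-side degree sequences from a truncated discrete power law,
#' reconciles their sums to the edge target (excess trimmed from the
#' largest-degree nodes, deficits added to the smallest), wires stubs by a
#' random matching, and collapses duplicate pairings (colliding stubs are
#' re-paired for up to 20 rounds before being dropped). The planted-block
#' model flips one coin per pair of the m x n grid. Identical seeds give
#' identical edge sets.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed.
#' @return A [bipartite_graph()] with labels `u001...` / `v001...`.
#' @examples
#' g <- generate_network(generator_spec("planted_block", m = 40, n = 40,
#'                                      blocks = 2), seed = 1)
#' network_stats(g)
#' @export
generate_network <- function(spec, seed) {
  if (!inherits(spec, "generator_spec")) stop("`spec` must come from generator_spec()")
  edges <- with_seed(seed, {
    if (spec$model == "configuration") {
      sample_configuration(spec)
    } else {
      sample_planted_block(spec)
    }
  })
  if (nrow(edges) == 0L) stop("generator produced no edges; increase density")
  wid <- function(k) formatC(seq_len(k), width = nchar(k), flag = "0")
  new_bipartite_graph(
    paste0("u", wid(spec$m)), paste0("v", wid(spec$n)),
    edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  )
}

# Truncated discrete power-law degree sample: P(k) ~ k^-gamma on
# min_deg..max_deg.
sample_powerlaw_degrees <- function(n_nodes, exponent, min_deg, max_deg) {
  ks <- min_deg:max_deg
  sample(ks, n_nodes, replace = TRUE, prob = ks^(-exponent))
}

# Mean of the truncated discrete power law; used to pick a minimum degree
# matching a requested mean.
powerlaw_mean <- function(exponent, min_deg, max_deg) {
  ks <- min_deg:max_deg
  w <- ks^(-exponent)
  sum(ks * w) / sum(w)
}

pick_min_degree <- function(exponent, target_mean, max_deg) {
  cand <- seq_len(min(20L, max_deg))
  mu <- vapply(cand, function(x) powerlaw_mean(exponent, x, max_deg), numeric(1))
  cand[which.min(abs(mu - target_mean))]
}

# Adjust a degree vector so it sums to `target`: decrement the current
# maximum while too large, increment the current minimum (respecting the
# cap) while too small. Deterministic given the input.
reconcile_degrees <- function(d, target, cap) {
  s <- sum(d)
  while (s > target) {
    i <- which.max(d)
    if (d[i] <= 1L) break
    d[i] <- d[i] - 1L
    s <- s - 1L
  }
  while (s < target) {
    i <- which.min(replace(d, d >= cap, .Machine$integer.max))
    if (!is.finite(d[i]) || d[i] >= cap) break
    d[i] <- d[i] + 1L
    s <- s + 1L
  }
  d
}

sample_configuration <- function(spec) {
  m <- spec$m
  n <- spec$n
  target <- spec$target_edges
  mins <- spec$min_degree
  if (is.null(mins)) {
    mins <- c(
      pick_min_degree(spec$exponent[1L], target / m, n),
      pick_min_degree(spec$exponent[2L], target / n, m)
    )
  }
  dl <- sample_powerlaw_degrees(m, spec$exponent[1L], mins[1L], n)
  dr <- sample_powerlaw_degrees(n, spec$exponent[2L], mins[2L], m)
  dl <- reconcile_degrees(dl, target, n)
  dr <- reconcile_degrees(dr, target, m)
  if (sum(dl) != sum(dr)) {
    # caps prevented one side from reaching the target; shrink to the
    # smaller total so the stub sets stay matched
    tot <- min(sum(dl), sum(dr))
    dl <- reconcile_degrees(dl, tot, n)
    dr <- reconcile_degrees(dr, tot, m)
  }
  ls <- rep.int(seq_len(m), dl)
  rs <- rep.int(seq_len(n), dr)
  rs <- rs[sample.int(length(rs))]
  key_seen <- integer(0)
  out_l <- integer(0)
  out_r <- integer(0)
  for (round in seq_len(20L)) {
    key <- (ls - 1L) * n + rs
    fresh <- !(key %in% key_seen) & !duplicated(key)
    out_l <- c(out_l, ls[fresh])
    out_r <- c(out_r, rs[fresh])
    key_seen <- c(key_seen, key[fresh])
    if (all(fresh)) break
    ls <- ls[!fresh]
    rs <- rs[!fresh]
    if (length(ls) <= 1L) break
    rs <- rs[sample.int(length(rs))]
  }
  cbind(out_l, out_r)
}

sample_planted_block <- function(spec) {
  bl_left <- sort(rep_len(seq_len(spec$blocks), spec$m))
  bl_right <- sort(rep_len(seq_len(spec$blocks), spec$n))
  p <- ifelse(
    outer(bl_left, bl_right, `==`),
    spec$p_within, spec$p_between
  )
  hit <- which(matrix(stats::runif(spec$m * spec$n), spec$m, spec$n) < p,
               arr.ind = TRUE)
  cbind(hit[, 1L], hit[, 2L])
}

#' Fit a discrete power-law exponent by maximum likelihood
#'
#' Fits `P(k) ~ k^-alpha` for `k >= xmin` to a sample of positive integers
#' (typically a degree sequence), maximizing the discrete likelihood with
#' the Hurwitz zeta normalizer (evaluated by Euler-Maclaurin summation).
#' When `xmin` is `NULL` the threshold is selected by the usual
#' Kolmogorov-Smirnov criterion: every viable threshold (at least 50 tail
#' observations, below the 90th percentile) is tried and the one whose
#' fitted tail tracks the empirical distribution most closely wins. This
#' makes the fit robust to departures from the power law at the smallest
#' degrees.
#'
#' @param x Positive integers (degrees).
#' @param xmin Smallest value included in the fit, or `NULL` to select it
#'   automatically.
#' @return A list with `exponent` (the MLE), `xmin`, `ks` (tail KS
#'   distance), and `n_tail` (sample size above the threshold).
#' @export
fit_power_law <- function(x, xmin = NULL) {
  x <- as.integer(x[x >= 1])
  if (is.null(xmin)) {
    cands <- sort(unique(x))
    n_tail <- vapply(cands, function(v) sum(x >= v), integer(1))
    cands <- cands[n_tail >= 50L & cands <= stats::quantile(x, 0.9)]
    if (length(cands) == 0L) cands <- min(x)
    fits <- lapply(cands, function(v) powerlaw_mle(x, v))
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]])
  }
  powerlaw_mle(x, as.integer(xmin))
}

powerlaw_mle <- function(x, xmin) {
  tail_x <- x[x >= xmin]
  if (length(tail_x) < 10L) stop("too few observations above `xmin` to fit")
  slx <- sum(log(tail_x))
  n <- length(tail_x)
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slx
  a_hat <- stats::optimize(nll, interval = c(1.05, 8))$minimum
  ks <- seq.int(xmin, max(tail_x))
  cdf_model <- cumsum(ks^(-a_hat)) / hurwitz_zeta(a_hat, xmin)
  ecdf_tail <- stats::ecdf(tail_x)
  ks_dist <- max(abs(cdf_model - ecdf_tail(ks)))
  list(exponent = a_hat, xmin = xmin, ks = ks_dist, n_tail = n)
}

# Hurwitz zeta(s, a) by direct summation plus Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a, nterms = 64L) {
  k <- 0:(nterms - 1L)
  head_sum <- sum((a + k)^(-s))
  b <- a + nterms
  head_sum + b^(1 - s) / (s - 1) + 0.5 * b^(-s) +
    s * b^(-s - 1) / 12 - s * (s + 1) * (s + 2) * b^(-s - 3) / 720
}
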