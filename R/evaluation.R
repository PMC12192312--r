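# Evaluation protocol: precision at a ranking cutoff, exact and sampled
# AUC, and repeated random-split experiments.

# Map probe label pairs onto row positions of a score table, validating
# coverage and disjointness from the training edges.
probe_positions <- function(scores, probe) {
  if (!inherits(scores, "score_table")) stop("`scores` must be a score_table")
  probe <- as.data.frame(probe, stringsAsFactors = FALSE)
  if (ncol(probe) < 2L || nrow(probe) == 0L) {
    stop("`probe` must be a non-empty two-column table of label pairs")
  }
  g <- attr(scores, "graph")
  if (!is.null(g)) {
    li <- match(as.character(probe[[1L]]), g$left_labels)
    ri <- match(as.character(probe[[2L]]), g$right_labels)
    if (anyNA(li) || anyNA(ri)) {
      k <- which(is.na(li) | is.na(ri))[1L]
      stop(sprintf("probe pair (%s, %s) names an unknown node", probe[k, 1L], probe[k, 2L]))
    }
    n <- n_right(g)
    in_train <- ((li - 1L) * n + ri) %in% ((g$edges[, 1L] - 1L) * n + g$edges[, 2L])
    if (any(in_train)) {
      k <- which(in_train)[1L]
      stop(sprintf(
        "probe pair (%s, %s) is an edge of the training graph",
        probe[k, 1L], probe[k, 2L]
      ))
    }
  }
  key <- paste(scores$left, scores$right, sep = "\r")
  pos <- match(paste(probe[[1L]], probe[[2L]], sep = "\r"), key)
  if (anyNA(pos)) {
    k <- which(is.na(pos))[1L]
    stop(sprintf(
      "probe pair (%s, %s) is missing from the score table", probe[k, 1L], probe[k, 2L]
    ))
  }
  unique(pos)
}

#' Precision at a ranking cutoff
#'
#' Ranks all scored candidates by score descending (ties broken by left
#' then right label in byte order), takes the top `L`, and returns the
#' fraction `L_r / L` of them that are probe (held-out) edges. `L`
#' defaults to the probe-set size.
#'
#' @param scores A `score_table` covering all candidates, probe pairs
#'   included.
#' @param probe Two-column table of held-out edge labels.
#' @param L Ranking cutoff; defaults to `nrow(probe)`.
#' @return Precision in `[0, 1]`, with the hit count attached as
#'   attribute `"Lr"`.
#' @export
precision_at <- function(scores, probe, L = NULL) {
  pos <- probe_positions(scores, probe)
  if (is.null(L)) L <- length(pos)
  L <- as.integer(L)
  if (L < 1L || L > nrow(scores)) {
    stop(sprintf("`L` must be between 1 and the candidate count (%d)", nrow(scores)))
  }
  ord <- score_order(scores)
  lr <- sum(pos %in% ord[seq_len(L)])
  structure(lr / L, Lr = lr, L = L)
}

#' Exact AUC of a score table against a probe set
#'
#' The probability that a randomly chosen probe (missing) edge outscores a
#' randomly chosen negative (non-edge, non-probe) candidate, with ties
#' counted one half. Computed exactly over all probe x negative
#' comparisons through a midrank statistic, so `AUC = (n' + 0.5 n'') / n`
#' with `n = n_pos * n_neg`.
#'
#' @inheritParams precision_at
#' @return AUC in `[0, 1]`, with comparison tallies `n`, `n_higher`
#'   (strict wins) and `n_tied` attached as attributes.
#' @export
auc_exact <- function(scores, probe) {
  pos <- probe_positions(scores, probe)
  np <- length(pos)
  nn <- nrow(scores) - np
  if (np == 0L) stop("probe set is empty")
  if (nn == 0L) stop("no negative candidates: probe covers every non-edge")
  x <- scores$score
  r <- rank(x, ties.method = "average")
  stat <- sum(r[pos]) - np * (np + 1) / 2
  # decompose into strict wins and ties for the Eq.-style tallies
  is_pos <- logical(length(x))
  is_pos[pos] <- TRUE
  ties <- 0
  tied_groups <- split(is_pos, x)
  for (grp in tied_groups) {
    ties <- ties + sum(grp) * sum(!grp)
  }
  n_higher <- stat - ties / 2
  structure(
    stat / (np * nn),
    n = np * nn, n_higher = n_higher, n_tied = ties
  )
}

#' Sampled AUC estimator
#'
#' Monte-Carlo estimate of [auc_exact()]: draws `n` independent
#' (probe, negative) comparisons with replacement and averages wins plus
#' half-ties. Reproducible through `seed`.
#'
#' @inheritParams precision_at
#' @param n Number of comparisons (>= 1).
#' @param seed Integer seed.
#' @return AUC estimate in `[0, 1]`.
#' @export
auc_sampled <- function(scores, probe, n, seed) {
  pos <- probe_positions(scores, probe)
  np <- length(pos)
  nn <- nrow(scores) - np
  if (np == 0L) stop("probe set is empty")
  if (nn == 0L) stop("no negative candidates: probe covers every non-edge")
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  ps <- scores$score[pos]
  ns <- scores$score[-pos]
  with_seed(seed, {
    a <- ps[sample.int(np, n, replace = TRUE)]
    b <- ns[sample.int(nn, n, replace = TRUE)]
    mean((a > b) + 0.5 * (a == b))
  })
}

#' Repeated random-split link-prediction experiment
#'
#' For each repetition r, splits the edges with seed `base_seed + r`,
#' scores every non-edge of the training graph under each method, and
#' computes precision (at `L`, defaulting to the probe size) and exact
#' AUC. Aggregates report the mean and sample standard deviation across
#' repetitions.
#'
#' @param graph The full observed `bipartite_graph`.
#' @param methods Character vector of method ids (see
#'   [available_methods()]).
#' @param train_fraction Fraction of edges used for training.
#' @param repetitions Number of independent splits (the headline protocol
#'   uses 100).
#' @param base_seed Integer; run r uses seed `base_seed + r`.
#' @param L Optional fixed precision cutoff.
#' @param config A [method_config()].
#' @return An `evaluation_result` list with data frames `per_run` and
#'   `aggregate` and the echoed parameters in `params`.
#' @examples
#' g <- toy_quadrangle()
#' run_experiment(g, "neiblp", train_fraction = 0.9, repetitions = 2, base_seed = 7)
#' @export
run_experiment <- function(graph, methods, train_fraction = 0.9,
                           repetitions = 100, base_seed = 1, L = NULL,
                           config = method_config()) {
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("`repetitions` must be at least 1")
  unknown <- setdiff(methods, available_methods())
  if (length(unknown) > 0L) {
    stop(sprintf(
      "unknown method(s) %s; available methods: %s",
      paste(sQuote(unknown), collapse = ", "),
      paste(available_methods(), collapse = ", ")
    ))
  }
  rows <- vector("list", repetitions * length(methods))
  k <- 0L
  for (r in seq_len(repetitions)) {
    seed_r <- as.integer(base_seed) + r
    sp <- split_edges(graph, train_fraction, seed = seed_r)
    for (mth in methods) {
      tab <- score_pairs(sp$train, mth, config = config)
      prec <- precision_at(tab, sp$probe, L = L)
      auc <- auc_exact(tab, sp$probe)
      k <- k + 1L
      rows[[k]] <- data.frame(
        method = mth, run = r, seed = seed_r,
        precision = as.numeric(prec), Lr = attr(prec, "Lr"), L = attr(prec, "L"),
        auc = as.numeric(auc), n_comparisons = attr(auc, "n"),
        n_candidates = nrow(tab), n_probe = nrow(sp$probe),
        stringsAsFactors = FALSE
      )
    }
  }
  per_run <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_run, per_run$method), function(d) {
    data.frame(
      method = d$method[1L],
      runs = nrow(d),
      mean_precision = mean(d$precision),
      sd_precision = stats::sd(d$precision),
      mean_auc = mean(d$auc),
      sd_auc = stats::sd(d$auc),
      stringsAsFactors = FALSE
    )
  }))
  agg <- agg[match(unique(per_run$method), agg$method), ]
  rownames(agg) <- NULL
  structure(
    list(
      per_run = per_run,
      aggregate = agg,
      params = list(
        methods = methods, train_fraction = train_fraction,
        repetitions = repetitions, base_seed = as.integer(base_seed),
        L = L
      )
    ),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "evaluation_result: p = %g, %d repetition(s), base seed %d\n",
    p$train_fraction, p$repetitions, p$base_seed
  ))
  print.data.frame(x$aggregate, digits = 4)
  invisible(x)
}

#' Write experiment results to disk
#'
#' Writes the per-run table as TSV and the aggregate (with the effective
#' parameters echoed for provenance) as JSON.
#'
#' @param result An `evaluation_result` from [run_experiment()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @export
write_evaluation <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!inherits(result, "evaluation_result")) {
    stop("`result` must be an evaluation_result")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      result$per_run, tsv_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = result$params, aggregate = result$aggregate),
      json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }
  invisible(result)
}
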