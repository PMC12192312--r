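# Shared miniature instance: matching graph plus one scored universe.
eval_fixture <- function(seed = 1, m = 5, n = 5, p = 0.35, method = "neiblp") {
  set.seed(seed)
  g <- rand_bigraph(m, n, p)
  sp <- split_edges(g, 0.8, seed = seed + 100)
  list(g = g, sp = sp, tab = score_pairs(sp$train, method))
}

test_that("precision follows the hit-count definition and tie rule", {
  fx <- eval_fixture(31, 6, 6, 0.4)
  tab <- fx$tab
  # force the probe pairs to the top: precision must be 1
  probe_keys <- paste(fx$sp$probe[, 1], fx$sp$probe[, 2], sep = "\r")
  boosted <- tab
  boosted$score[paste(tab$left, tab$right, sep = "\r") %in% probe_keys] <- 1e6
  expect_equal(as.numeric(precision_at(boosted, fx$sp$probe)), 1)

  # L = 4 with exactly one probe edge in the top 4
  tab2 <- tab
  tab2$score <- rev(seq_len(nrow(tab2)))  # strictly decreasing, distinct
  k <- which(paste(tab2$left, tab2$right, sep = "\r") %in% probe_keys)[1]
  tab2$score[k] <- nrow(tab2) + 1         # one probe first, others far down
  tab2$score[setdiff(which(paste(tab2$left, tab2$right, sep = "\r") %in% probe_keys), k)] <- 0
  expect_equal(as.numeric(precision_at(tab2, fx$sp$probe, L = 4)), 0.25)

  # all-tied scores resolve by the documented deterministic rule
  tab3 <- tab
  tab3$score <- rep(0.5, nrow(tab3))
  expect_equal(
    as.numeric(precision_at(tab3, fx$sp$probe, L = 2)),
    o_precision(tab3, probe_keys, 2)
  )

  expect_error(precision_at(tab, fx$sp$probe, L = 10^6), "candidate count")
})

test_that("precision is invariant to permuting distinct-score candidates", {
  fx <- eval_fixture(32, 6, 5, 0.4)
  tab <- fx$tab
  tab$score <- sample(seq_len(nrow(tab)))  # distinct
  perm <- sample(nrow(tab))
  tab_perm <- tab[perm, ]
  expect_equal(
    as.numeric(precision_at(tab, fx$sp$probe)),
    as.numeric(precision_at(tab_perm, fx$sp$probe))
  )
})

test_that("exact AUC obeys the separation, tie, and example laws", {
  fx <- eval_fixture(33, 6, 6, 0.4)
  tab <- fx$tab
  probe_keys <- paste(fx$sp$probe[, 1], fx$sp$probe[, 2], sep = "\r")
  is_probe <- paste(tab$left, tab$right, sep = "\r") %in% probe_keys

  sep <- tab; sep$score <- ifelse(is_probe, 2, 1)
  expect_equal(as.numeric(auc_exact(sep, fx$sp$probe)), 1)

  tied <- tab; tied$score <- 0
  expect_equal(as.numeric(auc_exact(tied, fx$sp$probe)), 0.5)

  # one positive at 0.9 against negatives {0.1, 0.9, ...}: check tallies
  a <- auc_exact(sep, fx$sp$probe)
  expect_equal(attr(a, "n"), sum(is_probe) * sum(!is_probe))
})

test_that("exact AUC equals the all-pairs double loop", {
  for (seed in 34:38) {
    fx <- eval_fixture(seed, 6, 6, 0.35)
    tab <- fx$tab
    # quantize scores to force ties
    tab$score <- round(tab$score, 1)
    probe_keys <- paste(fx$sp$probe[, 1], fx$sp$probe[, 2], sep = "\r")
    is_probe <- paste(tab$left, tab$right, sep = "\r") %in% probe_keys
    expect_equal(
      as.numeric(auc_exact(tab, fx$sp$probe)),
      o_auc(tab$score[is_probe], tab$score[!is_probe]),
      tolerance = 1e-12
    )
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  fx <- eval_fixture(39, 7, 6, 0.35)
  tab <- fx$tab
  base <- as.numeric(auc_exact(tab, fx$sp$probe))
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3 + x)) {
    tr <- tab
    tr$score <- f(tr$score)
    expect_equal(as.numeric(auc_exact(tr, fx$sp$probe)), base, tolerance = 1e-12)
  }
})

test_that("sampled AUC is reproducible and converges to the exact value", {
  fx <- eval_fixture(40, 7, 7, 0.35)
  s1 <- auc_sampled(fx$tab, fx$sp$probe, n = 500, seed = 77)
  s2 <- auc_sampled(fx$tab, fx$sp$probe, n = 500, seed = 77)
  expect_identical(s1, s2)

  # binomial error envelope: |sampled - exact| <= 3*sqrt(0.25/n) nearly always
  n_cmp <- 2000
  bound <- 3 * sqrt(0.25 / n_cmp)
  viol <- 0
  for (trial in 1:60) {
    fx <- eval_fixture(100 + trial, 6, 6, 0.4)
    ex <- as.numeric(auc_exact(fx$tab, fx$sp$probe))
    sm <- auc_sampled(fx$tab, fx$sp$probe, n = n_cmp, seed = trial)
    if (abs(sm - ex) > bound) viol <- viol + 1
  }
  expect_lte(viol, 2)
})

test_that("degenerate single-positive comparisons behave", {
  g <- bipartite_graph(data.frame(c("a", "a", "b"), c("x", "y", "x")))
  sp <- split_edges(g, 2 / 3, seed = 3)
  tab <- score_pairs(sp$train, "ra")
  tab$score <- ifelse(paste(tab$left, tab$right) %in%
                        paste(sp$probe[, 1], sp$probe[, 2]), 1, 0)
  if (nrow(tab) - nrow(sp$probe) >= 1) {
    expect_equal(auc_sampled(tab, sp$probe, n = 10, seed = 1), 1)
  }
  expect_error(auc_exact(tab, cbind(character(0), character(0))), "non-empty")
})

test_that("probe validation rejects training edges and unknown pairs", {
  fx <- eval_fixture(41, 6, 6, 0.4)
  train_edge <- cbind(
    left_labels(fx$sp$train)[fx$sp$train$edges[1, 1]],
    right_labels(fx$sp$train)[fx$sp$train$edges[1, 2]]
  )
  expect_error(auc_exact(fx$tab, train_edge), "edge of the training graph")
  expect_error(precision_at(fx$tab, cbind("nope", "nah")), "unknown node")
})

test_that("a single experiment run equals the manual composition", {
  set.seed(55)
  g <- rand_bigraph(8, 8, 0.35)
  res <- run_experiment(g, c("ra", "neiblp"), train_fraction = 0.8,
                        repetitions = 1, base_seed = 10)
  sp <- split_edges(g, 0.8, seed = 11)  # base_seed + run index
  for (mth in c("ra", "neiblp")) {
    tab <- score_pairs(sp$train, mth)
    row <- res$per_run[res$per_run$method == mth, ]
    expect_equal(row$precision, as.numeric(precision_at(tab, sp$probe)))
    expect_equal(row$auc, as.numeric(auc_exact(tab, sp$probe)))
    expect_equal(row$n_candidates, n_left(g) * n_right(g) - n_edges(sp$train))
  }
})

test_that("uninformative constant scores give AUC one half", {
  # a perfect matching has no L3 paths, so common-neighbor scores are all 0
  g <- bipartite_graph(data.frame(paste0("a", 1:10), paste0("b", 1:10)))
  res <- run_experiment(g, "cn", train_fraction = 0.9, repetitions = 5,
                        base_seed = 42)
  expect_true(all(res$per_run$auc == 0.5))
  expect_equal(res$aggregate$mean_auc, 0.5)
})

test_that("experiment rejects unknown methods and degenerate splits", {
  g <- bipartite_graph(data.frame(paste0("a", 1:4), paste0("b", 1:4)))
  expect_error(run_experiment(g, "nope", repetitions = 1), "available methods")
  tiny <- bipartite_graph(data.frame(c("a", "b"), c("x", "y")))
  expect_error(
    run_experiment(tiny, "cn", train_fraction = 0.95, repetitions = 1),
    "degenerate"
  )
})

test_that("evaluation files are written and reproducible", {
  set.seed(66)
  g <- rand_bigraph(7, 7, 0.4)
  res <- run_experiment(g, "ra", train_fraction = 0.8, repetitions = 2,
                        base_seed = 5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_evaluation(res, tsv_path = tsv, json_path = json)
  per_run <- utils::read.delim(tsv)
  expect_equal(nrow(per_run), 2L)
  agg <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(agg$aggregate$mean_auc, res$aggregate$mean_auc, tolerance = 1e-12)
})
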