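test_that("common-neighbor indices reproduce the toy and chain values", {
  a <- toy_cn_lcl("a")
  expect_equal(neighborhood_score(a, "u", "v", "cn"), 6)
  g <- path_graph()
  expect_equal(neighborhood_score(g, "u", "v", "cn"), 2)  # members {s, t}
  expect_equal(neighborhood_score(g, "u", "v", "jc"), 1)
  expect_equal(neighborhood_score(g, "u", "v", "ra"), 1)
  g2 <- bipartite_graph(data.frame(c("u", "t"), c("s", "v")))
  for (mth in c("cn", "jc", "aa", "ra")) {
    expect_equal(neighborhood_score(g2, "u", "v", mth), 0)
  }
  expect_error(neighborhood_score(g, "s", "v", "cn"), "not a left-side")
})

test_that("local community indices count the links between neighborhoods", {
  expect_equal(lcp_score(toy_cn_lcl("a"), "u", "v", "lcl"), 5)
  expect_equal(lcp_score(toy_cn_lcl("b"), "u", "v", "lcl"), 6)
  g <- path_graph()
  expect_equal(lcp_score(g, "u", "v", "lcl"), 1)
  expect_equal(lcp_score(g, "u", "v", "car"), 2)
})

test_that("neighborhood and community scores match set-expansion oracles", {
  set.seed(707)
  for (rep in 1:30) {
    g <- rand_bigraph(sample(4:9, 1), sample(4:9, 1), 0.3)
    B <- o_dense(g)
    kv <- colSums(B); ku <- rowSums(B)
    ne <- all_non_edges(g)
    for (k in seq_len(min(nrow(ne), 4))) {
      i <- ne[k, 1]; j <- ne[k, 2]
      mem <- o_cn_members(B, i, j)
      kz <- c(kv[mem$right], ku[mem$left])
      expect_true(all(kz >= 2))  # members always lie on an L3 path
      expect_equal(neighborhood_score(g, i, j, "cn"), length(kz))
      expect_equal(
        neighborhood_score(g, i, j, "jc"),
        if (length(kz) == 0) 0 else length(kz) / (ku[i] + kv[j])
      )
      expect_equal(neighborhood_score(g, i, j, "aa"),
                   if (length(kz) == 0) 0 else sum(1 / log2(kz)))
      expect_equal(neighborhood_score(g, i, j, "ra"),
                   if (length(kz) == 0) 0 else sum(1 / kz))
      lcl <- o_lcl(B, i, j)
      expect_equal(lcp_score(g, i, j, "lcl"), lcl)
      expect_equal(lcp_score(g, i, j, "car"), length(kz) * lcl)
      gz <- c(
        vapply(mem$right, function(s) sum(B[, s] * B[, j]), numeric(1)),
        vapply(mem$left, function(t) sum(B[t, ] * B[i, ]), numeric(1))
      )
      expect_equal(lcp_score(g, i, j, "caa"),
                   if (length(kz) == 0) 0 else sum(gz / log2(kz)))
      expect_equal(lcp_score(g, i, j, "cra"),
                   if (length(kz) == 0) 0 else sum(gz / kz))
      if (lcl == 0) {
        expect_equal(lcp_score(g, i, j, "car"), 0)
        expect_equal(neighborhood_score(g, i, j, "cn"), 0)
      }
    }
  }
})

test_that("path indices equal dense adjacency-power oracles", {
  g <- path_graph()
  expect_equal(path_score(g, "u", "v", "lp3"), 1)
  # damped odd-walk series on the chain, expected value from the oracle
  B <- o_dense(g)
  w5 <- o_walks(B, 1, 2, 5)
  w7 <- o_walks(B, 1, 2, 7)
  cfg <- method_config(beta = 0.5, max_odd_length = 7)
  expect_equal(path_score(g, "u", "v", "lpop", cfg),
               0.5^3 * 1 + 0.5^5 * w5 + 0.5^7 * w7)

  set.seed(808)
  for (rep in 1:20) {
    g <- rand_bigraph(sample(4:10, 1), sample(4:10, 1), 0.3)
    B <- o_dense(g)
    ne <- all_non_edges(g)
    cfg <- method_config(beta = 0.2, max_odd_length = 7)
    for (k in seq_len(min(nrow(ne), 3))) {
      i <- ne[k, 1]; j <- ne[k, 2]
      expect_equal(path_score(g, i, j, "lp3"), o_walks(B, i, j, 3), tolerance = 1e-12)
      expect_equal(path_score(g, i, j, "lp35", cfg),
                   o_walks(B, i, j, 3) + 0.2 * o_walks(B, i, j, 5), tolerance = 1e-12)
      expect_equal(path_score(g, i, j, "lpop", cfg),
                   0.2^3 * o_walks(B, i, j, 3) + 0.2^5 * o_walks(B, i, j, 5) +
                     0.2^7 * o_walks(B, i, j, 7),
                   tolerance = 1e-12)
      # intermediate-degree normalization
      P <- o_paths3(B, i, j)
      l3_expect <- if (is.null(P)) 0 else {
        sum(1 / sqrt(colSums(B)[P[, 1]] * rowSums(B)[P[, 2]]))
      }
      expect_equal(path_score(g, i, j, "l3"), l3_expect, tolerance = 1e-12)
      # endpoint normalization variant
      raw <- o_walks(B, i, j, 3)
      ep <- if (raw == 0) 0 else raw / (rowSums(B)[i] * colSums(B)[j])
      expect_equal(
        path_score(g, i, j, "l3", method_config(l3_norm = "endpoint")),
        ep, tolerance = 1e-12
      )
    }
  }
})

test_that("the untruncated odd-walk series demands convergence", {
  set.seed(4)
  g <- rand_bigraph(6, 6, 0.5)
  expect_error(
    path_score(g, all_non_edges(g)[1, 1], all_non_edges(g)[1, 2], "lpop",
               method_config(beta = 5, max_odd_length = Inf)),
    "diverges"
  )
  # convergent closed form approximates a deep truncation
  cfg_inf <- method_config(beta = 0.05, max_odd_length = Inf)
  cfg_trunc <- method_config(beta = 0.05, max_odd_length = 21)
  ne <- all_non_edges(g)
  i <- ne[1, 1]; j <- ne[1, 2]
  expect_equal(path_score(g, i, j, "lpop", cfg_inf),
               path_score(g, i, j, "lpop", cfg_trunc), tolerance = 1e-8)
})

test_that("projection scores equal the explicit resource-spreading oracle", {
  g <- path_graph()
  expect_equal(projection_score(g, "u", "v", "nbi"), 0.25)
  expect_equal(projection_score(g, "u", "v", "bpr"), 0.25)

  set.seed(909)
  for (rep in 1:20) {
    g <- rand_bigraph(sample(4:10, 1), sample(4:10, 1), 0.3)
    B <- o_dense(g)
    ne <- all_non_edges(g)
    for (k in seq_len(min(nrow(ne), 4))) {
      i <- ne[k, 1]; j <- ne[k, 2]
      expect_equal(projection_score(g, i, j, "nbi"), o_nbi(B, i, j), tolerance = 1e-12)
      # the mirrored process gives the same mass on undirected networks
      expect_equal(projection_score(g, i, j, "bpr"),
                   projection_score(g, i, j, "nbi"), tolerance = 1e-12)
    }
  }
})

test_that("isolated endpoints score zero under every method", {
  # a node whose only edge lands in the probe set is isolated in training
  sp <- split_edges(bipartite_graph(data.frame(c("a", "a", "b", "c"),
                                               c("x", "y", "x", "z"))),
                    train_fraction = 0.75, seed = 9)
  iso_left <- names(which(degrees(sp$train, "left") == 0))
  for (mth in available_methods()) {
    tab <- score_pairs(sp$train, mth)
    expect_true(all(is.finite(tab$score)))
    expect_true(all(tab$score >= 0))
    if (length(iso_left) > 0) {
      expect_true(all(tab$score[tab$left %in% iso_left] == 0))
    }
  }
})

test_that("unknown methods are rejected with the available list", {
  g <- path_graph()
  expect_error(score_pairs(g, "katz"), "available methods")
})
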