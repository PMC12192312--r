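---
title: "Quadrangle-based link prediction in bipartite networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrangle-based link prediction in bipartite networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neiblp)
```

## The problem and the model

An undirected, unweighted bipartite network G(U, V, E) — drugs against
target proteins, genes against sequence motifs, members against events —
admits edges only across its two node sets. Link prediction ranks the
unobserved pairs H − E of the m × n grid by a similarity score S_uv, under
the usual assumption that structurally similar pairs are more likely to be
missing edges than true negatives.

Bipartiteness breaks the classical common-neighbor machinery: a left node u
and a right node v can never share a direct neighbor. The shortest possible
route between them is a length-three (L3) path u–s–t–v through one
right-side intermediate s and one left-side intermediate t. All local
structure relevant to the pair therefore lives in its *quadrangle graph*
Q_uv: the union of all L3 paths between u and v ([`enumerate_l3()`]
returns the path set P_uv = {(s, t) : s ∈ Γ(u), t ∈ Γ(s) ∩ Γ(v)}).

Real bipartite networks are strongly degree-heterogeneous — a few hubs, a
long tail of low-degree nodes — so raw path or neighbor counts are dominated
by hub-mediated paths that carry little pair-specific information. The
package's core index treats that heterogeneity explicitly and splits the
quadrangle structure by node role:

* **Cross-type component (QDRA).** A resource-allocation sum over the
  distinct paths, `qdra(g, u, v) = sum over (s,t) in P_uv of 1/(k_s k_t)`,
  with degrees taken in the full training graph. Each path is discounted by
  both of its intermediate degrees.
* **Same-type component (QSRA).** Same-side nodes can be compared through
  shared opposite-side neighbors: `stra(a, b) = sum over x in
  Γ(a)∩Γ(b) of 1/k_x`. With T and S the distinct left and right
  intermediates of P_uv, `qsra(g, u, v)` is the product of the two factor
  sums `[Σ_{t∈T} stra(u, t)] × [Σ_{s∈S} stra(v, s)]`. The product form means
  the term vanishes unless *both* sides of the quadrangle reinforce the
  pair.
* **Combined score.** `neiblp_score = qdra + qsra`, deliberately
  parameter-free: both components are on the same resource-allocation scale
  and capture complementary structure, so they are summed with unit
  weights, and the package provides no knob to re-weight them.

Every node on an L3 path has at least one training edge, so no degree in
these sums can be zero; all scores are finite and non-negative by
construction, and they are exactly zero when P_uv is empty.

### A structural identity and the fast path

For any left intermediate t of P_uv, the common neighbors of u and t are
*exactly* the right partners of t within P_uv: any additional shared
neighbor x would satisfy x ∈ Γ(u), t ∈ Γ(x), t ∈ Γ(v) and hence be a path
(x, t) itself. Consequently, on candidate non-edges

* `qdra` equals the (u, v) entry of B D_V⁻¹ Bᵀ D_U⁻¹ B,
* `qsra` equals the entrywise product of B D_V⁻¹ Bᵀ B and B Bᵀ D_U⁻¹ B,

with B the sparse biadjacency and D the degree diagonals. [`score_pairs()`]
uses these sparse products to score all candidates at once; the per-pair
functions remain the definition of correctness and the test suite asserts
agreement to 1e-12. The identity also shows why the same-type factor sums
printed in worked examples sometimes look like per-node STRA expansions:
they are, but the node sets involved are fully determined by the path set.

## Baseline indices

The comparison methods follow their standard bipartite forms, with the
common-neighbor set defined by quadratic closure,
CN(u, v) = (Γ(u) ∩ Γ̂(v)) ∪ (Γ̂(u) ∩ Γ(v)) where Γ̂ is the same-side
two-hop neighborhood. Members of CN(u, v) always lie on an L3 path and so
have degree ≥ 2 — the logarithmic weights of `aa`/`caa` can never divide by
log 1. Notes on points where conventions in the literature diverge:

* **`aa`** uses `1/log2(k_z)`; the resource-allocation variant `ra` uses
  `1/k_z`. (Printed formula tables occasionally conflate the two; they are
  kept distinct here, since otherwise the indices coincide.)
* **`l3`** defaults to intermediate-degree normalization, each path
  weighted `1/sqrt(k_s k_t)` — the form that actually mitigates
  intermediate-degree bias. A variant normalizing the raw count by the
  endpoint degrees `|Γ(u)||Γ(v)|` is available via
  `method_config(l3_norm = "endpoint")`.
* **`lp3`** is the length-3 entry of the cubed full adjacency matrix. On a
  bipartite graph this coincides with **`lcl`**, the count of local
  community links (edges between Γ(u) and Γ(v)): both equal (B Bᵀ B)_uv.
  Both ids are kept because they anchor different index families (`lp35`,
  `lpop` vs. `car`, `caa`, `cra`).
* **`lp35`** adds `beta` times the *fifth*-power walk count (default
  `beta = 0.1`). Note that matrix powers count walks, not simple paths;
  the length-5 entry of A⁵ includes backtracking walks.
* **`lpop`** is the damped odd-length walk series Σ βˡ (Aˡ)_uv. The
  conventional `beta = 1/λ_max` (the default; λ_max is the top singular
  value of B, found by power iteration) puts the series exactly at its
  radius of convergence, so the package always truncates — default
  `max_odd_length = 21`. The closed form β B (I − β² BᵀB)⁻¹ is available
  via `max_odd_length = Inf` and refuses to run unless `β λ_max < 1`.
* **`nbi` / `bpr`** are two-step mass-conserving resource-allocation
  projections, spreading from u's neighborhood (right→left→right) and from
  v's neighborhood (left→right→left) respectively. For undirected,
  unweighted networks the two directions are *algebraically identical* —
  each spreading step normalizes by the sending node's degree, and the
  senders are always the two intermediates, so both reduce to
  B D_V⁻¹ Bᵀ D_U⁻¹ B. Both ids are exposed; their agreement is asserted in
  the tests rather than assumed.

## Evaluation protocol

`split_edges()` removes a uniform random subset of edges: `round(p·|E|)`
edges (ties to even) form the training graph, the rest the probe set. No
connectivity repair is attempted — a node whose edges are all removed
simply scores zero against everything, which is the honest behavior of a
local index under data loss. The candidate universe is every non-edge of
the *training* graph, so probe edges compete against all true negatives.

* **Precision at L** (`precision_at`): fraction of the top-L ranked
  candidates that are probe edges, L defaulting to the probe size. Ranking
  ties are broken deterministically — score descending, then left and then
  right label in byte (C-locale radix) order. The tie rule is a
  reproducibility choice, not a statistical one; it is documented, applied
  identically in file output (`write_scores`, 10 significant digits,
  byte-identical across runs), and exhaustively checked against a
  reference ranking in the tests.
* **AUC** (`auc_exact`): the probability that a random probe edge outscores
  a random negative, ties at one half. The default is the *exact*
  expectation over all probe × negative pairs via a midrank statistic,
  removing estimator noise; the sampled estimator of n independent
  comparisons (`auc_sampled`) is retained for protocol fidelity and obeys
  the binomial error envelope.
* **Experiments** (`run_experiment`): repetition r splits with seed
  `base_seed + r`, scores, and records both metrics; aggregates report
  means with sample standard deviations. Everything is reproducible from
  the base seed, and the CLI echoes the effective configuration into its
  JSON output.

## Synthetic generators: what they emulate, and what they do not

Two models (`generator_spec()` / `generate_network()`):

* **Configuration model** — emulates the heavy-tailed degree
  heterogeneity of real interaction networks. Per-side degrees are drawn
  from a truncated discrete power law; the defaults (m = n = 500, exponent
  2.5, mean degree 8) sit in the size/sparsity regime of typical curated
  interaction datasets. The minimum degree is derived from the requested
  mean through the truncated zeta mean (3 for the defaults); degree sums
  are reconciled to the edge target by trimming excess stubs from the
  largest-degree nodes (preserving the tail's shape) and adding deficits
  to the smallest (raising the floor, not the tail); stubs are wired by a
  random matching and duplicate pairings are re-matched for up to 20
  rounds before the remainder is dropped. Duplicate losses at the
  defaults average ~2% of the edge target.
* **Planted blocks** — matched left/right blocks with dense within-block
  and sparse background probabilities (defaults: 4 blocks of 30 × 30,
  within 0.5, background 0.02). This gives ground-truth structure on
  which ranking quality is genuinely measurable — any competent local
  index recovers held-out within-block edges.

Two honest caveats determine what passing tests on these networks show
about real data. First, planted blocks have near-binomial (homogeneous)
degrees, so they exercise the *pipeline* (split, score, rank, aggregate)
but not the degree-heterogeneity correction: on such networks the
same-type term adds no measurable ranking signal beyond the cross-type
term, and the two are statistically tied. The ablation direction — the
combined index not ranking worse than its cross-type component — is
therefore asserted on configuration-model networks, where the margin is
systematic. Second, neither generator reproduces degree correlations,
nestedness, or community-degree coupling of real networks; results on
them are sanity floors, not performance claims.

`fit_power_law()` closes the loop on the first generator: a discrete
maximum-likelihood fit with the Hurwitz zeta normalizer (Euler–Maclaurin
evaluation), selecting the tail threshold by the standard
Kolmogorov–Smirnov criterion (at least 50 tail observations, threshold at
most the 90th percentile). Threshold selection matters here because the
sum-reconciliation step distorts the distribution exactly at the minimum
degree; the KS rule lets the fit start above that region. Parameter
recovery of the planted exponent is part of the test suite.

## Numerical and design choices

* **Determinism.** All randomness flows through explicit seeds, restored
  after use; all orderings use locale-independent radix sorting; score
  files are written in binary mode with fixed `%.9e` formatting, so equal
  configurations give byte-identical files on any platform.
* **Pinned toys.** The shipped toy networks (`toy_quadrangle()`,
  `toy_cn_lcl()`) are code-built synthetic stand-ins, frozen by md5
  checksum and pinned by their defining quantities: the quadrangle toy by
  component values 1/12 and 7/12 for its focal pair, the common-neighbor
  trio by CN = 6 with LCL 5/6/6 and a degree rearrangement that only a
  degree-aware index separates. Tests assert the pinned values, not the
  file bytes, so the topologies are falsifiable.
* **Problem sizes in tests.** Oracle-equivalence checks run on hundreds of
  random graphs with m + n ≤ 40 against dense triple-loop and
  matrix-power references; benchmark properties use 20-seed batches of
  120 × 120 (blocks) and 500 × 500 (configuration) networks. These sizes
  make every brute-force oracle exact and the whole suite quick to run,
  while remaining large enough for the stochastic assertions to be
  stable.
* **Isolated nodes and degenerate inputs.** Degree reciprocals are defined
  as zero for isolated nodes (their scores are zero everywhere);
  empty candidate sets yield empty tables; empty inputs, malformed rows
  (reported with line numbers), same-side node pairs, probe/training
  overlap, and degenerate splits are all rejected with specific errors.

## Limitations

Scores are purely structural: node attributes, edge weights, and temporal
information are out of scope, as are learned or factorization-based
predictors. The m × n score matrix is materialized densely during bulk
scoring, which is comfortable to ~10⁶ pairs but not beyond; per-pair
functions remain available at any scale. The toy fixtures are
demonstrations, not data; and as discussed above, synthetic benchmarks
bound sanity, not real-world performance.
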