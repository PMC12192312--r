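# Pinned toy networks.
#
# These small fixtures ship as edge-list TSV resources under extdata and
# are frozen by md5 checksums; the values they are pinned to (CN, LCL,
# QDRA, QSRA of the focal pair) are asserted by the test suite. They are
# code-built synthetic stand-ins whose purpose is to exhibit, at desk
# scale, the structural situations that motivate the quadrangle-based
# index.

FIXTURE_MD5 <- c(
  toy_quadrangle.tsv = "f3e7b0968ec86a86a4e9920b64693820",
  toy_cn_lcl_a.tsv = "232cc728dbbb6074dbb4d95f021365d8",
  toy_cn_lcl_b.tsv = "a1c936f559c221b72cf6b6c7227a7a94",
  toy_cn_lcl_c.tsv = "8ef46f119d6fe5a6dc5a736dd7281cd8"
)

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "neiblp", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[file]]))) {
    stop(sprintf("fixture '%s' is corrupted (md5 %s)", file, sum))
  }
  read_edge_list(path)
}

#' Worked-example quadrangle network
#'
#' A 20-node toy network built around an unconnected focal pair (`u`, `v`)
#' whose quadrangle graph runs through a single right-side hub `s` (degree
#' 12) and seven left-side intermediates `t1`..`t7` (degrees 8 and 6,
#' chosen so that `sum(1/k_t) = 1`). The focal pair has
#' `qdra(u, v) = 1/12` and `qsra(u, v) = 7/12` exactly, which makes the
#' network a convenient end-to-end check of the scoring pipeline.
#'
#' @return A [bipartite_graph()].
#' @examples
#' g <- toy_quadrangle()
#' qdra(g, "u", "v") * 12
#' @export
toy_quadrangle <- function() read_fixture("toy_quadrangle.tsv")

#' Common-neighbor indistinguishability toys
#'
#' Three variants of an 8-node network in which the focal pair (`u`, `v`)
#' always has the same six common neighbors `u1..u3, v1..v3`, so the CN
#' index cannot separate them. Variant `"a"` has 5 local community links;
#' `"b"` adds one more (LCL 6, `v1` of degree 3); `"c"` keeps CN = 6 and
#' LCL = 6 but rewires the community links so `v1` has degree 4 — only a
#' degree-aware index such as NeiBLP tells `"b"` and `"c"` apart.
#'
#' @param variant `"a"`, `"b"`, or `"c"`.
#' @return A [bipartite_graph()].
#' @examples
#' lcp_score(toy_cn_lcl("a"), "u", "v", "lcl")
#' @export
toy_cn_lcl <- function(variant = c("a", "b", "c")) {
  variant <- match.arg(variant)
  read_fixture(sprintf("toy_cn_lcl_%s.tsv", variant))
}
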