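test_that("DDN fixtures attain and respect the node-count bound", {
  # chain D -> M -> S: one intermediate, bound met with equality (3 = 1+1+1)
  u <- build_ughp(list(make_pathway("c", c("D", "M"), c("M", "S"))))
  ddn <- build_ddn(u, "D", "S")
  expect_setequal(ddn$nodes, c("D", "M", "S"))
  expect_equal(ddn$intermediate_genes, "M")
  expect_equal(length(ddn$nodes),
               length(ddn$drug_genes) + length(ddn$disease_genes) +
                 length(ddn$intermediate_genes))

  # adjacent drug and disease gene: no intermediate, strict inequality vs 3
  u2 <- build_ughp(list(make_pathway("a", "D", "S")))
  ddn2 <- build_ddn(u2, "D", "S")
  expect_setequal(ddn2$nodes, c("D", "S"))
  expect_length(ddn2$intermediate_genes, 0L)

  # two drug genes sharing one intermediate: counted once, < naive sum
  u3 <- build_ughp(list(make_pathway("y", c("D1", "D2", "M"),
                                     c("M", "M", "S"))))
  ddn3 <- build_ddn(u3, c("D1", "D2"), "S")
  expect_setequal(ddn3$nodes, c("D1", "D2", "M", "S"))
  oracle <- union(
    bf_shortest_path_nodes(u3$edges, u3$nodes, "D1", "S")$nodes,
    bf_shortest_path_nodes(u3$edges, u3$nodes, "D2", "S")$nodes)
  expect_setequal(ddn3$nodes, oracle)
})

test_that("DDN drops unmapped genes, counts unreachable pairs, partitions roles", {
  u <- build_ughp(list(make_pathway("c", c("D", "M", "X"), c("M", "S", "Y"))))
  ddn <- build_ddn(u, c("D", "NOTINGRAPH"), c("S", "X"))
  expect_equal(ddn$n_drug_unmapped, 1L)
  # D-X unreachable (X in the separate component): endpoints only
  expect_equal(ddn$unreachable_pairs, 1L)
  expect_true(all(c("D", "S", "X") %in% ddn$nodes))
  expect_length(intersect(ddn$drug_genes, ddn$intermediate_genes), 0L)
  expect_length(intersect(ddn$disease_genes, ddn$intermediate_genes), 0L)

  # gene on both sides categorized once
  ddn2 <- build_ddn(u, c("D", "S"), c("S"))
  expect_equal(ddn2$both_genes, "S")
  expect_lte(length(ddn2$nodes),
             length(ddn2$drug_genes) + length(ddn2$disease_genes) +
               length(ddn2$intermediate_genes))

  # all of one side unmapped signals a degenerate (undefined-score) DDN
  ddn3 <- build_ddn(u, "NOPE", "S")
  expect_true(ddn3$degenerate)
  sc <- score_ddn(ddn3, make_profile("d", c(S = 1, M = 2, D = 3)),
                  make_signature(c(S = 1, M = 2, D = 3)))
  expect_false(sc$defined)
})

test_that("DDN node sets match brute-force enumeration on random graphs", {
  for (seed in 1:20) {
    p <- random_pathway(15L, 30L, seed = 3000L + seed)
    u <- build_ughp(list(p))
    set.seed(seed)
    dr <- sample(u$nodes, 3L)
    di <- sample(setdiff(u$nodes, dr), 2L)
    for (directed in c(FALSE, TRUE)) {
      ddn <- build_ddn(u, dr, di, directed = directed)
      oracle <- sort(unique(unlist(lapply(dr, function(s) {
        unlist(lapply(di, function(t) {
          bf_shortest_path_nodes(p$edges, u$nodes, s, t, directed = directed)$nodes
        }))
      }))))
      expect_equal(ddn$nodes, oracle,
                   info = sprintf("seed %d directed %s", seed, directed))
    }
  }
})

test_that("the repurposing score is the Pearson correlation of the z arrays", {
  u <- build_ughp(list(make_pathway("c", c("g1", "g2"), c("g2", "g3"))))
  ddn <- build_ddn(u, "g1", "g3")
  sig <- make_signature(c(g1 = 1, g2 = 2, g3 = 3))

  rev <- make_profile("rev", c(g1 = -1, g2 = -2, g3 = -3))
  expect_equal(score_ddn(ddn, rev, sig)$r, -1)
  same <- make_profile("same", c(g1 = 1, g2 = 2, g3 = 3))
  expect_equal(score_ddn(ddn, same, sig)$r, 1)

  # hand case on four genes: r = 0.8
  u4 <- build_ughp(list(make_pathway("c4", c("a", "b", "c"), c("b", "c", "d"))))
  ddn4 <- build_ddn(u4, "a", "d")
  sc <- score_ddn(ddn4, make_profile("d", c(a = 1, b = 3, c = 2, d = 4)),
                  make_signature(c(a = 1, b = 2, c = 3, d = 4)))
  expect_equal(sc$r, 0.8, tolerance = 1e-12)
  expect_equal(sc$n_genes_scored, 4L)

  # zero variance or < 3 genes: undefined, not an error
  expect_false(score_ddn(ddn, make_profile("f", c(g1 = 1, g2 = 1, g3 = 1)),
                         sig)$defined)
  expect_false(score_ddn(build_ddn(u, "g1", "g2"),
                         make_profile("d", c(g1 = 1, g2 = 2)), sig)$defined)
})

test_that("score matches a textbook correlation oracle and ignores gene order", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(3:40, 1L)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(ddnscreen:::pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
  # permutation invariance through the full scoring path
  genes <- sprintf("g%02d", 1:10)
  p <- make_pathway("p", genes[1:9], genes[2:10])
  u <- build_ughp(list(p))
  ddn <- build_ddn(u, genes[1], genes[10])
  set.seed(5)
  z1 <- stats::setNames(rnorm(10), genes)
  z2 <- stats::setNames(rnorm(10), genes)
  perm <- sample(10L)
  s1 <- score_ddn(ddn, make_profile("d", z1), make_signature(z2))
  s2 <- score_ddn(ddn, make_profile("d", z1[perm]),
                  make_signature(z2[rev(perm)]))
  expect_equal(s1$r, s2$r, tolerance = 1e-15)
})

test_that("ranking sorts defined scores ascending with lexicographic ties", {
  mk_score <- function(key, r, defined = TRUE) {
    structure(list(drug_key = key, drug_id = sub("\\|.*", "", key),
                   dose = 10, time_h = 24, subtype_id = "S1",
                   r = r, defined = defined, n_genes_scored = 10L),
              class = "repurposing_score")
  }
  rk <- rank_drugs(list(mk_score("d1|10|24", -0.5), mk_score("d2|10|24", 0.3),
                        mk_score("d3|10|24", -0.9)))
  expect_equal(rk$drug_id, c("d3", "d1", "d2"))
  expect_equal(rk$rank, 1:3)

  expect_equal(nrow(rank_drugs(list(mk_score("d1|10|24", NA, FALSE)))), 0L)

  tie <- rank_drugs(list(mk_score("b|10|24", -0.5), mk_score("a|10|24", -0.5)))
  expect_equal(tie$drug_key, c("a|10|24", "b|10|24"))

  best <- rank_drugs(list(mk_score("a|10|24", -0.5), mk_score("a|0.04|24", -0.7),
                          mk_score("b|10|24", -0.6)), best_per_drug = TRUE)
  expect_equal(best$drug_key, c("a|0.04|24", "b|10|24"))
})

test_that("score distributions summarize the five numbers", {
  mk <- function(r) structure(list(drug_key = "k", drug_id = "k", dose = 1,
                                   time_h = 24, subtype_id = "S1", r = r,
                                   defined = TRUE, n_genes_scored = 5L),
                              class = "repurposing_score")
  d <- score_distribution(list(mk(-0.2), mk(0), mk(0.2)))
  expect_equal(d$median, 0)
  expect_equal(d$n, 3L)
  one <- score_distribution(list(mk(0.4)))
  expect_true(all(unlist(one[c("min", "q1", "median", "q3", "max")]) == 0.4))
})
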