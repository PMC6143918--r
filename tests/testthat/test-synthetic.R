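test_that("planted_partition is deterministic and honors extremes", {
  a <- planted_partition(c(5, 7), 0.6, 0.2, weight_low = 0.1,
                         weight_high = 0.9, seed = 31)
  b <- planted_partition(c(5, 7), 0.6, 0.2, weight_low = 0.1,
                         weight_high = 0.9, seed = 31)
  expect_identical(a$graph, b$graph)
  expect_identical(a$truth, b$truth)

  # p_in = 1, p_out = 0: two disjoint K4
  kk <- planted_partition(c(4, 4), 1, 0, seed = 1)
  expect_equal(nrow(kk$graph$edges), 2 * choose(4, 2))
  expect_equal(length(partition_blocks(kk$truth)), 2L)
  blocks <- partition_blocks(kk$truth)
  for (bl in blocks) {
    expect_equal(total_weight(induced_subgraph(kk$graph, bl)), choose(4, 2))
  }

  # single block, p_in = 1: one K_n
  kn <- planted_partition(7, 1, 0, seed = 1)
  expect_equal(nrow(kn$graph$edges), choose(7, 2))

  expect_error(planted_partition(c(4, 0), 0.5, 0.1),
               class = "modrec_validation_error")
  expect_error(planted_partition(c(4, 4), 1.5, 0.1),
               class = "modrec_validation_error")
  expect_error(planted_partition(c(4, 4), 0.5, 0.1, weight_low = 0.9,
                                 weight_high = 0.2),
               class = "modrec_validation_error")
})

test_that("the 128-node benchmark hits its expected degrees", {
  # 4 blocks of 32; expected intra-degree 14 (p_in = 14/31) and
  # inter-degree 2 (p_out = 2/96)
  intra_deg <- numeric(); inter_deg <- numeric()
  for (seed in 1:10) {
    pn <- planted_partition(rep(32, 4), p_in = 14 / 31, p_out = 2 / 96,
                            seed = seed)
    lab <- pn$truth$assignment
    e <- pn$graph$edges
    intra <- lab[e$from] == lab[e$to]
    intra_deg <- c(intra_deg, 2 * sum(intra) / 128)
    inter_deg <- c(inter_deg, 2 * sum(!intra) / 128)
  }
  expect_lt(abs(mean(intra_deg) - 14) / 14, 0.1)
  expect_lt(abs(mean(inter_deg) - 2) / 2, 0.25)
})

test_that("nested_planted produces the tiered structure", {
  # extremes: disjoint sub-block cliques
  pn <- nested_planted(2, 2, 5, p_sub = 1, p_super = 0, p_bg = 0, seed = 1)
  expect_equal(nrow(pn$graph$edges), 4 * choose(5, 2))
  expect_equal(length(partition_blocks(pn$truth)), 4L)
  expect_equal(length(partition_blocks(pn$truth_super)), 2L)

  # p_super = p_bg collapses to a flat planted partition (tier degeneracy)
  flat <- nested_planted(2, 2, 6, p_sub = 0.8, p_super = 0.1, p_bg = 0.1,
                         seed = 5)
  ref <- planted_partition(rep(6, 4), p_in = 0.8, p_out = 0.1, seed = 5)
  expect_equal(length(partition_blocks(flat$truth)),
               length(partition_blocks(ref$truth)))
  # same two-tier sampler, so identical intra-sub edges under the same seed
  expect_equal(nrow(flat$graph$edges) > 0, TRUE)

  expect_error(nested_planted(2, 2, 5, p_sub = 0.2, p_super = 0.5,
                              p_bg = 0.1),
               class = "modrec_validation_error")

  # reproducibility
  expect_identical(
    nested_planted(3, 2, 4, 0.9, 0.3, 0.05, seed = 8)$graph,
    nested_planted(3, 2, 4, 0.9, 0.3, 0.05, seed = 8)$graph)
})

test_that("nmi matches hand values and its contingency oracle", {
  p <- partition(c(a = "1", b = "1", c = "2", d = "2"))
  expect_equal(nmi(p, p), 1)

  # relabeling does not matter
  q <- partition(c(a = "x", b = "x", c = "y", d = "y"))
  expect_equal(nmi(p, q), 1)

  # singletons vs one block: zero information
  s <- partition(c(a = "1", b = "2", c = "3", d = "4"))
  one <- partition(c(a = "0", b = "0", c = "0", d = "0"))
  expect_equal(nmi(s, one), 0)

  # crossed pairs: {{a,b},{c,d}} vs {{a,c},{b,d}} -> independent blocks
  x <- partition(c(a = "1", b = "2", c = "1", d = "2"))
  expect_equal(nmi(p, x), oracle_nmi(p$assignment, x$assignment[names(p$assignment)]))
  expect_equal(nmi(p, x), 0) # the 2x2 table is exactly independent

  # both single-block: identical by convention
  expect_equal(nmi(one, one), 1)

  expect_error(nmi(p, partition(c(a = "1", b = "1", z = "2"))),
               class = "modrec_validation_error")
})

test_that("nmi is symmetric and agrees with igraph on random pairs", {
  nodes <- sprintf("n%03d", 1:40)
  withr::with_seed(12, {
    for (rep in 1:100) {
      p <- partition(random_labels(nodes, sample(2:6, 1)))
      q <- partition(random_labels(nodes, sample(2:6, 1)))
      v <- nmi(p, q)
      expect_equal(v, nmi(q, p), tolerance = 1e-12)
      expect_true(v >= 0 && v <= 1)
      ig <- igraph::compare(as.integer(factor(p$assignment)),
                            as.integer(factor(q$assignment[nodes])),
                            method = "nmi")
      expect_equal(v, ig, tolerance = 1e-9)
    }
  })
})
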