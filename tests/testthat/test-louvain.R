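test_that("modularity matches hand values and the dense oracle", {
  # all-in-one partition scores exactly 0 on any graph
  for (seed in 1:5) {
    pn <- planted_partition(c(5, 6), 0.7, 0.3, weight_low = 0.1,
                            weight_high = 1, seed = seed)
    one <- fx_partition(list(pn$graph$nodes))
    expect_equal(modularity(pn$graph, one), 0, tolerance = 1e-12)
  }

  # two equal disjoint cliques, one community each: Q = 1/2
  tt <- fx_two_triangles()
  expect_equal(modularity(tt, fx_partition(list(c("a", "b", "c"),
                                                c("x", "y", "z")))), 0.5)

  # singleton-partitioned unit triangle: Q = -1/3
  tri <- fx_clique(3)
  expect_equal(modularity(tri, singleton_partition(tri)), -1 / 3)

  # random partitions agree with the independent dense evaluation
  withr::with_seed(99, {
    for (rep in 1:10) {
      pn <- planted_partition(c(6, 6), 0.8, 0.3, seed = rep)
      labels <- random_labels(pn$graph$nodes, 3)
      expect_equal(modularity(pn$graph, partition(labels)),
                   oracle_modularity(pn$graph, labels), tolerance = 1e-12)
    }
  })

  # self-loops enter through A_ii = 2 * loop
  gl <- weighted_graph(edges = data.frame(from = "a", to = "b", weight = 1),
                       self_loops = c(a = 0.5))
  labels <- c(a = "1", b = "2")
  expect_equal(modularity(gl, partition(labels)),
               oracle_modularity(gl, labels), tolerance = 1e-12)

  expect_error(modularity(weighted_graph(nodes = c("a", "b")),
                          partition(c(a = "1", b = "1"))),
               class = "modrec_validation_error")
})

test_that("local moves find the planted split and respect local optima", {
  g <- fx_barbell(4)
  p <- local_move_phase(g, singleton_partition(g), rng_seed = 1)
  expect_setequal(lapply(partition_blocks(p), sort),
                  list(sprintf("a%d", 1:4), sprintf("b%d", 1:4)))

  # an input already at a local optimum is returned unchanged
  tt <- fx_two_triangles()
  opt <- fx_partition(list(c("a", "b", "c"), c("x", "y", "z")))
  moved <- local_move_phase(tt, opt, rng_seed = 1)
  expect_equal(partition_blocks(moved)[[1]], partition_blocks(opt)[[1]])
  expect_equal(length(partition_blocks(moved)), 2L)

  # single edge: merging beats the singleton start (Q = 0 > -1/2)
  se <- weighted_graph(edges = data.frame(from = "a", to = "b", weight = 1))
  pm <- local_move_phase(se, singleton_partition(se), rng_seed = 1)
  expect_equal(length(partition_blocks(pm)), 1L)
})

test_that("aggregation preserves total weight and structure", {
  tt <- fx_two_triangles()
  agg <- aggregate_communities(tt, fx_partition(list(c("a", "b", "c"),
                                                     c("x", "y", "z"))))
  expect_equal(length(agg$graph$nodes), 2L)
  expect_equal(nrow(agg$graph$edges), 0L)
  expect_equal(unname(agg$graph$self_loops), c(3, 3))
  expect_equal(total_weight(agg$graph), total_weight(tt))

  # singleton partition: aggregation is the identity up to node names
  g <- fx_barbell(3)
  agg1 <- aggregate_communities(g, singleton_partition(g))
  expect_equal(total_weight(agg1$graph), total_weight(g))
  expect_equal(nrow(agg1$graph$edges), nrow(g$edges))

  # barbell with the clique partition: bridge becomes the inter-edge
  b <- fx_barbell(4)
  agg2 <- aggregate_communities(b, fx_partition(list(sprintf("a%d", 1:4),
                                                     sprintf("b%d", 1:4))))
  expect_equal(agg2$graph$edges$weight, 1)
  expect_equal(unname(agg2$graph$self_loops), c(6, 6))
  # strengths survive aggregation
  expect_equal(sum(node_strength(agg2$graph)), sum(node_strength(b)))
})

test_that("louvain reaches the exhaustive optimum on small fixtures", {
  fixtures <- list(barbell = fx_barbell(4),
                   two_triangles = fx_two_triangles(),
                   k5 = fx_clique(5),
                   path3 = fx_path3(),
                   star = fx_star(3),
                   ring6 = fx_ring(6))
  for (name in names(fixtures)) {
    g <- fixtures[[name]]
    best <- oracle_max_modularity(g)
    q_louvain <- modularity(g, louvain(g, rng_seed = 7))
    expect_gte(best$q + 1e-12, q_louvain)
    if (name %in% c("barbell", "two_triangles", "k5")) {
      expect_equal(q_louvain, best$q, tolerance = 1e-12)
    }
  }
})

test_that("a whole clique is never split", {
  g <- fx_clique(5)
  p <- louvain(g, rng_seed = 3)
  expect_equal(length(partition_blocks(p)), 1L)
  expect_equal(modularity(g, p), 0)
})

test_that("louvain honors the initial partition and never degrades it", {
  tt <- fx_two_triangles()
  opt <- fx_partition(list(c("a", "b", "c"), c("x", "y", "z")))
  res <- louvain(tt, init = opt, rng_seed = 5)
  expect_equal(length(partition_blocks(res)), 2L)
  expect_equal(modularity(tt, res), 0.5)

  # monotonicity from arbitrary (bad) seeds
  withr::with_seed(4, {
    for (rep in 1:8) {
      pn <- planted_partition(c(8, 8, 8), 0.7, 0.1, seed = rep)
      init <- partition(random_labels(pn$graph$nodes, 4))
      res <- louvain(pn$graph, init = init, rng_seed = rep)
      expect_gte(modularity(pn$graph, res),
                 modularity(pn$graph, init) - 1e-12)
    }
  })
})

test_that("louvain is reproducible under a fixed seed", {
  pn <- planted_partition(c(16, 16, 16), 0.6, 0.05, weight_low = 0.2,
                          weight_high = 1, seed = 8)
  a <- louvain(pn$graph, rng_seed = 123)
  b <- louvain(pn$graph, rng_seed = 123)
  expect_identical(a, b)
})

test_that("incremental Q bookkeeping matches from-scratch recomputation", {
  pn <- planted_partition(c(10, 10, 10), 0.8, 0.1, weight_low = 0.3,
                          weight_high = 1, seed = 21)
  g <- pn$graph
  checked <- 0L
  local_move_phase(g, singleton_partition(g), rng_seed = 2,
                   on_move = function(p, q_incremental) {
                     checked <<- checked + 1L
                     expect_equal(q_incremental, modularity(g, p),
                                  tolerance = 1e-10)
                   })
  expect_gt(checked, 10L)
})
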