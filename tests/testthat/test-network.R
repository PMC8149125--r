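edge_df <- function(a, b, w, score = FALSE) {
  if (score) data.frame(node_a = a, node_b = b, combined_score = w)
  else data.frame(node_a = a, node_b = b, weight = w)
}

test_that("PPI construction applies a strict threshold and the score dialect", {
  # all weights at or below the threshold: edgeless graph over restrict_to
  g0 <- build_ppi_network(edge_df(c("a", "b"), c("b", "c"), c(0.7, 0.5)),
                          restrict_to = c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 4)   # isolates retained

  # 0-1000 integer dialect: 700 -> 0.700 is not > 0.7; 701 is
  g1 <- build_ppi_network(edge_df(c("a", "b"), c("b", "c"), c(700, 701),
                                  score = TRUE))
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$weight, 0.701)

  g2 <- build_ppi_network(edge_df("a", "b", 0.71))
  expect_equal(igraph::ecount(g2), 1)

  expect_error(build_ppi_network(edge_df("a", "b", -0.1)), "weights")
  expect_error(build_ppi_network(edge_df("a", "b", 1200)), "weights")
})

test_that("edges leaving the restricted set are dropped", {
  g <- build_ppi_network(edge_df(c("a", "a"), c("b", "x"), c(0.9, 0.9)),
                         restrict_to = c("a", "b"))
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("a", "b"))
})

test_that("betweenness follows the pairwise shortest-path definition", {
  path3 <- build_ppi_network(edge_df(c("a", "b"), c("b", "c"), c(0.9, 0.9)))
  ct <- node_centrality(path3)
  expect_equal(ct$betweenness[match(c("a", "b", "c"), ct$node)], c(0, 1, 0))

  star <- build_ppi_network(edge_df(rep("c", 3), c("l1", "l2", "l3"),
                                    rep(0.9, 3)))
  cs <- node_centrality(star)
  expect_equal(cs$betweenness[cs$node == "c"], 3)

  expect_equal(nrow(node_centrality(igraph::make_empty_graph(0, directed = FALSE))), 0)
})

test_that("betweenness matches exhaustive path enumeration on random graphs", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.45) adj[i, j] <- adj[j, i] <- 1
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("n%d", seq_len(n))
    got <- node_centrality(g)$betweenness
    expect_equal(got, betweenness_oracle(adj), tolerance = 1e-9)
  }
})

test_that("average connectivity includes isolates and rejects empty graphs", {
  tri <- build_ppi_network(edge_df(c("a", "b", "c"), c("b", "c", "a"),
                                   rep(0.9, 3)))
  expect_equal(average_connectivity(tri), list(mean_degree = 2,
                                               mean_betweenness = 0))
  p3 <- build_ppi_network(edge_df(c("a", "b"), c("b", "c"), c(0.9, 0.9)))
  ac <- average_connectivity(p3)
  expect_equal(ac$mean_degree, 4 / 3)
  expect_equal(ac$mean_betweenness, 1 / 3)
  iso <- build_ppi_network(edge_df("a", "b", 0.1),
                           restrict_to = sprintf("x%d", 1:5))
  expect_equal(average_connectivity(iso), list(mean_degree = 0,
                                               mean_betweenness = 0))
  expect_error(average_connectivity(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("community detection separates disconnected cliques and is labelled contiguously", {
  cl <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(5))
  igraph::V(cl)$name <- sprintf("v%d", 1:10)
  part <- detect_communities(cl, n_trials = 3, rng_seed = 1)
  expect_equal(n_clusters(part), 2)
  expect_equal(sort(unique(part$assignment)), c(1L, 2L))
  expect_length(unique(part$assignment[1:5]), 1)
  expect_length(unique(part$assignment[6:10]), 1)

  empty <- detect_communities(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(n_clusters(empty), 0)
})

test_that("the best codelength never worsens as trials accumulate", {
  set.seed(21)
  ppi <- gen_ppi_edges(ppi_config(n_blocks = 4, block_size = 12,
                                  p_within = 0.4, p_between = 0.03,
                                  background_size = 48, seed = 3))
  g <- build_ppi_network(ppi$edges)
  quals <- vapply(c(1, 3, 6, 10), function(k) {
    detect_communities(g, n_trials = k, rng_seed = 17)$quality
  }, numeric(1))
  expect_true(all(diff(quals) <= 1e-12))
})

test_that("size filtering removes only sub-threshold communities", {
  a <- setNames(c(1L, 1L, 1L, 1L, 2L, 3L, 3L, 3L),
                sprintf("n%d", 1:8))
  part <- xconcord:::new_partition(a)
  f <- filter_small_clusters(part, min_size = 4)
  expect_equal(n_clusters(f), 1)              # the size-4 community survives
  expect_equal(sum(is.na(f$assignment)), 4)   # singleton + size-3 removed
  expect_equal(sum(!is.na(f$assignment)) + sum(is.na(f$assignment)), 8)
  # all communities at or above the threshold: identity
  big <- xconcord:::new_partition(setNames(rep(1:2, each = 4), sprintf("m%d", 1:8)))
  expect_equal(filter_small_clusters(big)$assignment, big$assignment)
  expect_error(filter_small_clusters(part, min_size = 0), "min_size")
})

test_that("whole network pipeline is invariant to node order up to relabeling", {
  set.seed(5)
  ppi <- gen_ppi_edges(ppi_config(n_blocks = 3, block_size = 10,
                                  p_within = 0.5, p_between = 0.02,
                                  background_size = 30, seed = 9))
  e1 <- ppi$edges
  e2 <- e1[sample.int(nrow(e1)), ]
  g1 <- build_ppi_network(e1)
  g2 <- build_ppi_network(e2)
  p1 <- detect_communities(g1, rng_seed = 4)
  p2 <- detect_communities(g2, rng_seed = 4)
  common <- igraph::V(g1)$name
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(p1$assignment[common],
                                         p2$assignment[common]), 1)
})

test_that("connectivity null flags a saturated draw as degenerate and is seeded", {
  edges <- edge_df(c("a", "b", "c"), c("b", "c", "a"), rep(0.9, 3))
  expect_error(connectivity_null(edges, observed = c("a", "b", "c"),
                                 background = c("a", "b", "c"), B = 20,
                                 metrics = "mean_degree", rng_seed = 1),
               "degenerate")
  set.seed(31)
  ppi <- gen_ppi_edges(ppi_config(n_blocks = 2, block_size = 10,
                                  p_within = 0.6, background_size = 120,
                                  seed = 12))
  n1 <- connectivity_null(ppi$edges, observed = ppi$module,
                          background = ppi$background, B = 50,
                          metrics = "mean_degree", rng_seed = 8)
  n2 <- connectivity_null(ppi$edges, observed = ppi$module,
                          background = ppi$background, B = 50,
                          metrics = "mean_degree", rng_seed = 8)
  expect_identical(n1$mean_degree$samples, n2$mean_degree$samples)
  expect_error(connectivity_null(ppi$edges, ppi$module, ppi$background,
                                 k = 1000, B = 10), "exceeds")
})
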