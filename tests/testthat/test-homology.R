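map_df <- function(sa, ga, sb, gb, score = NULL) {
  df <- data.frame(species_a = sa, gene_a = ga, species_b = sb, gene_b = gb,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- score
  df
}

test_that("merging homology maps unions nodes and edges into a simple graph", {
  g <- build_merged_graph(list(map_df("human", "H1", "mouse", "M1"),
                               map_df("mouse", "M1", "fly", "F1")))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::components(g)$no, 1)

  # duplicated edges across maps collapse; duplication is idempotent
  g2 <- build_merged_graph(list(map_df("human", "H1", "mouse", "M1"),
                                map_df("human", "H1", "mouse", "M1")))
  expect_equal(igraph::ecount(g2), 1)

  empty <- build_merged_graph(list())
  expect_equal(igraph::vcount(empty), 0)

  expect_error(build_merged_graph(list(map_df("human", "H1", "human", "H2"))),
               "same species")
})

test_that("min_score drops weak homology edges but default keeps everything", {
  m <- map_df("human", c("H1", "H2"), "fly", c("F1", "F2"), score = c(1, 9))
  expect_equal(igraph::ecount(build_merged_graph(list(m))), 2)
  expect_equal(igraph::ecount(build_merged_graph(list(m), min_score = 3)), 1)
})

test_that("a component covering all species marks every member concordant", {
  g <- build_merged_graph(list(
    map_df("human", c("H1", "H2"), "fly", c("F1", "F1")),
    map_df("mouse", "M1", "fly", "F1")))
  fit <- concordant_components(
    g, list(human = c("H1", "H2"), mouse = "M1", fly = "F1"), "up")
  expect_equal(fit$n_components, 1)
  expect_equal(fit$n_concordant_components, 1)
  expect_equal(fit$counts[["human"]], 2)   # divergence: both human genes count

  # missing species: not concordant
  fit2 <- concordant_components(
    build_merged_graph(list(map_df("human", "H1", "mouse", "M1"))),
    list(human = "H1", mouse = "M1"), "up")
  expect_equal(fit2$n_concordant_components, 0)

  # empty DEG sets: no components
  fit3 <- concordant_components(g, list(human = character()), "up")
  expect_equal(fit3$n_components, 0)

  expect_error(concordant_components(g, list(human = "H1"), "up",
                                     required_species = c("human", "worm")),
               "unknown required_species")
})

test_that("fly-condition partition separates glia- and neuron-driven concordance", {
  g <- build_merged_graph(list(
    map_df("human", c("H1", "H2"), "mouse", c("M1", "M2")),
    map_df("mouse", c("M1", "M2"), "fly", c("F1", "F2"))))
  res <- partition_by_fly_condition(g, human_degs = c("H1", "H2"),
                                    mouse_degs = c("M1", "M2"),
                                    fly_glia_degs = "F1",
                                    fly_neuron_degs = "F2",
                                    direction = "up")
  expect_equal(res$glia, "H1")
  expect_equal(res$neuron, "H2")
  expect_length(res$both, 0)
  expect_setequal(res$union, c("H1", "H2"))

  same <- partition_by_fly_condition(g, c("H1", "H2"), c("M1", "M2"),
                                     c("F1", "F2"), c("F1", "F2"), "up")
  expect_equal(same$glia, same$neuron)
  expect_equal(same$both, same$glia)

  none <- partition_by_fly_condition(g, c("H1", "H2"), c("M1", "M2"),
                                     character(), character(), "up")
  expect_length(none$union, 0)
})

test_that("orthology absence is judged on the full merged graph", {
  g <- build_merged_graph(list(map_df("human", "H1", "mouse", "M1"),
                               map_df("human", "H2", "mouse", "M2"),
                               map_df("mouse", "M2", "fly", "F1")))
  # H1's component lacks fly; H2's has it; H9 is absent from the graph
  expect_setequal(genes_without_ortholog(c("H1", "H2", "H9"), "human", g, "fly"),
                  c("H1", "H9"))
  expect_error(genes_without_ortholog("H1", "human", g, "worm"), "unknown")
})

test_that("concordance respects set conservation, symmetry and monotonicity", {
  set.seed(41)
  for (rep in 1:25) {
    u <- random_universe_edges(20, 35)
    g <- build_merged_graph(list(u$edges))
    degs <- lapply(u$pools, function(p) sample(p, 10))
    fit <- concordant_components(g, degs, "up")

    # conservation: per-species member counts equal induced node counts
    vsp <- igraph::V(g)$species
    vgn <- igraph::V(g)$gene
    for (s in names(degs)) {
      expect_equal(sum(fit$components$species == s),
                   sum(vsp == s & vgn %in% degs[[s]]))
    }

    # species relabeling symmetry: swapping mouse and fly everywhere
    # permutes the roles but preserves the human concordant set
    swap <- function(x) c(human = "human", mouse = "fly", fly = "mouse")[x]
    e2 <- u$edges
    e2$species_a <- swap(e2$species_a)
    e2$species_b <- swap(e2$species_b)
    g2 <- build_merged_graph(list(e2))
    degs2 <- list(human = degs$human, mouse = degs$fly, fly = degs$mouse)
    fit2 <- concordant_components(g2, degs2, "up")
    expect_equal(fit$concordant_genes$human, fit2$concordant_genes$human)

    # monotonicity: adding a DEG never removes a concordant gene
    degs3 <- degs
    degs3$human <- union(degs3$human, sample(u$pools$human, 1))
    fit3 <- concordant_components(g, degs3, "up")
    for (s in names(degs)) {
      expect_true(all(fit$concordant_genes[[s]] %in% fit3$concordant_genes[[s]]))
    }

    # two-species concordance is a superset of the tri-species one
    hm <- concordant_components(g, degs, "up",
                                required_species = c("human", "mouse"))
    expect_true(all(fit$concordant_genes$human %in% hm$concordant_genes$human))
    expect_true(all(fit$concordant_genes$mouse %in% hm$concordant_genes$mouse))
  }
})

test_that("node insertion order does not change concordance calls", {
  u <- random_universe_edges(15, 25)
  g1 <- build_merged_graph(list(u$edges))
  g2 <- build_merged_graph(list(u$edges[rev(seq_len(nrow(u$edges))), ]))
  degs <- lapply(u$pools, function(p) p[1:8])
  f1 <- concordant_components(g1, degs, "down")
  f2 <- concordant_components(g2, degs, "down")
  expect_equal(f1$concordant_genes, f2$concordant_genes)
  expect_equal(f1$n_concordant_components, f2$n_concordant_components)
})
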