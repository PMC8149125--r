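test_that("universe generation realizes the requested homology topology", {
  # pure one-to-one: every non-orphan component has one gene per species
  u11 <- gen_universe(universe_config(
    n_genes = 30, mix = c(one_to_one = 1, one_to_many = 0, many_to_many = 0,
                          orphan = 0), seed = 2))
  tr <- u11$truth
  per_comp <- split(tr, tr$component_id)
  expect_true(all(vapply(per_comp, nrow, integer(1)) == 3))
  expect_true(all(vapply(per_comp, function(d) length(unique(d$species)),
                         integer(1)) == 3))

  # pure orphans: no edges at all
  uo <- gen_universe(universe_config(
    n_genes = 10, mix = c(one_to_one = 0, one_to_many = 0, many_to_many = 0,
                          orphan = 1), seed = 2))
  expect_length(uo$maps, 0)
  expect_true(all(uo$truth$type == "orphan"))

  # an infeasibly small universe for a requested topology errors
  expect_error(gen_universe(universe_config(
    n_genes = 3, mix = c(one_to_one = 0, one_to_many = 0.1,
                         many_to_many = 0, orphan = 0.9))), "infeasible")

  # determinism: same config, same universe
  a <- gen_universe(universe_config(n_genes = 40, seed = 7))
  b <- gen_universe(universe_config(n_genes = 40, seed = 7))
  expect_identical(a, b)
  expect_error(universe_config(mix = c(one_to_one = 0.5, one_to_many = 0.5,
                                       many_to_many = 0.2, orphan = 0)),
               "summing to 1")
})

test_that("one-to-many and many-to-many components are connected and typed", {
  u <- gen_universe(universe_config(
    n_genes = 60, mix = c(one_to_one = 0.3, one_to_many = 0.3,
                          many_to_many = 0.2, orphan = 0.2), seed = 4))
  g <- build_merged_graph(u$maps)
  comp <- igraph::components(g)
  tr <- u$truth[u$truth$type != "orphan", ]
  # the generator's component map coincides with graph components
  key <- paste(tr$species, tr$gene_id, sep = ":")
  expect_equal(length(unique(tr$component_id)), comp$no)
  got <- comp$membership[key]
  expect_equal(length(unique(paste(tr$component_id, got))),
               length(unique(tr$component_id)))
  # many_to_many components carry >= 2 genes in >= 2 species
  mm <- split(tr[tr$type == "many_to_many", ], tr$component_id[tr$type == "many_to_many"])
  expect_true(all(vapply(mm, function(d) {
    sum(table(d$species) >= 2) >= 2
  }, logical(1))))
})

test_that("planted DE signal makes components concordant by construction", {
  u <- gen_universe(universe_config(n_genes = 200, seed = 5))
  deg <- gen_deg_stats(u, plant_config(n_concordant_up = 10,
                                       n_concordant_down = 10,
                                       n_extra = c(human = 20, mouse = 20, fly = 20),
                                       seed = 6))
  # planted members share their component's direction in every species
  mem <- deg$truth$members
  per <- split(mem$direction, mem$component_id)
  expect_true(all(vapply(per, function(d) length(unique(d)) == 1, logical(1))))

  # all-null planting yields pure-null tables
  null <- gen_deg_stats(u, plant_config(n_concordant_up = 0,
                                        n_concordant_down = 0,
                                        n_extra = c(human = 0, mouse = 0, fly = 0),
                                        seed = 6))
  expect_equal(nrow(null$truth$members), 0)
  expect_gt(suppressWarnings(ks.test(null$mouse$p_value, "punif")$p.value), 0.01)

  # infeasible planting errors
  expect_error(gen_deg_stats(u, plant_config(n_concordant_up = 10000)),
               "cannot plant")

  # determinism
  expect_identical(gen_deg_stats(u, plant_config(seed = 9)),
                   gen_deg_stats(u, plant_config(seed = 9)))
})

test_that("end-to-end recovery of planted components through filter and concordance", {
  hits <- vapply(1:20, function(s) {
    u <- gen_universe(universe_config(
      n_genes = 150, mix = c(one_to_one = 1, one_to_many = 0,
                             many_to_many = 0, orphan = 0), seed = s))
    deg <- gen_deg_stats(u, plant_config(n_concordant_up = 10,
                                         n_concordant_down = 10,
                                         n_extra = c(human = 10, mouse = 10, fly = 10),
                                         seed = s + 500))
    g <- build_merged_graph(u$maps)
    calls <- list(human = call_degs_human(deg$human_probes, fc_dialect = "linear"),
                  mouse = call_degs_any_contrast(deg$mouse),
                  fly = call_degs_any_contrast(rbind(deg$fly$glia, deg$fly$neuron)))
    rec <- vapply(c("up", "down"), function(d) {
      fit <- concordant_components(g, list(
        human = deg_gene_set(calls$human, d),
        mouse = deg_gene_set(calls$mouse, d),
        fly = deg_gene_set(calls$fly, d)), d)
      mem <- deg$truth$members
      md <- mem[mem$direction == d, ]
      mean(vapply(split(md, md$component_id), function(cm) {
        all(mapply(function(gn, sp) gn %in% fit$concordant_genes[[sp]],
                   cm$gene_id, cm$species))
      }, logical(1)))
    }, numeric(1))
    mean(rec)
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.9)
})

test_that("planted-partition edges respect probabilities and weight ranges", {
  ppi <- gen_ppi_edges(ppi_config(n_blocks = 3, block_size = 10,
                                  p_within = 0.5, p_between = 0,
                                  background_size = 30, background_degree = 0,
                                  seed = 8))
  # with no between-block and no background edges, every edge stays inside
  # its planted block, so blocks are disconnected components
  blk <- setNames(ppi$truth$block, ppi$truth$node)
  expect_true(all(blk[ppi$edges$node_a] == blk[ppi$edges$node_b]))
  expect_true(all(ppi$edges$weight >= 0 & ppi$edges$weight <= 1))
  expect_identical(gen_ppi_edges(ppi_config(seed = 3)),
                   gen_ppi_edges(ppi_config(seed = 3)))
})

test_that("behavior generator plants exact multiplicative improvements", {
  beh <- gen_behavior(behavior_config(noise_sd = 0, seed = 1),
                      genotypes = data.frame(genotype = "mod",
                                             improvement = 0.2))
  rec <- beh$records
  # noiseless: the day-averaged relative difference equals the plant exactly
  expect_equal(percent_improvement(rec[rec$genotype == "mod", ],
                                   rec[rec$genotype == "posctrl", ]), 20,
               tolerance = 1e-12)
  expect_true(all(rec$speed >= 0))
  expect_identical(gen_behavior(behavior_config(seed = 2)),
                   gen_behavior(behavior_config(seed = 2)))
})

test_that("a simulated study round-trips through its plain-text files", {
  sim <- simulate_study(seed = 12)
  outdir <- tempfile("sim")
  write_simulation(sim, outdir)
  probes <- read_tsv_mapped(file.path(outdir, "human_probes.tsv"))
  expect_equal(nrow(probes), nrow(sim$deg$human_probes))
  expect_equal(probes$p_value, sim$deg$human_probes$p_value)
  m <- read_homology_map(list.files(outdir, "homology_", full.names = TRUE)[1])
  expect_true(all(c("species_a", "gene_a", "species_b", "gene_b") %in% names(m)))
  g1 <- build_merged_graph(lapply(list.files(outdir, "homology_",
                                             full.names = TRUE),
                                  read_homology_map))
  g2 <- build_merged_graph(sim$universe$maps)
  expect_equal(igraph::vcount(g1), igraph::vcount(g2))
  expect_equal(igraph::ecount(g1), igraph::ecount(g2))
  bg <- readLines(file.path(outdir, "background_proteome.txt"))
  expect_setequal(bg, sim$ppi$background)
  unlink(outdir, recursive = TRUE)
})
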