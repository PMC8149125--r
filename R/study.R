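#' Simulate a full study with the shape of the cross-species HD analysis
#'
#' One call generates every pipeline input with the statistical structure
#' the analysis assumes: a tri-species gene universe under a mixed-topology
#' homology map, planted concordantly dysregulated components split across
#' fly driver conditions, per-species DE summary tables (human probe-level,
#' mouse continuous-trait, fly drivers x models x timepoints), a
#' planted-partition interaction network over the concordant human genes
#' embedded in a large background proteome, and longitudinal climbing
#' trajectories with tiered planted improvements.
#'
#' The `"study-shape"` preset is a desk-scale tri-species screen design:
#' 3,000/3,600/3,200 genes for human/mouse/fly; 160 concordant components
#' planted per direction split 40/30/30% across the both/glia-only/
#' neuron-only fly conditions; two fly models x three timepoints per driver;
#' a 15,884-protein background; five shared 20-gene interaction blocks plus
#' one glia-specific and one neuron-specific block; six screen genotypes
#' with improvements from +40% down to -15%.
#'
#' @param preset currently `"study-shape"`.
#' @param seed integer master seed; module seeds are derived from it.
#' @return list with elements `universe`, `deg`, `ppi`, `behavior`,
#'   `network_inputs` (block gene sets used for the planted networks) and
#'   `seed`.
#' @export
simulate_study <- function(preset = "study-shape", seed = 1L) {
  preset <- match.arg(preset)
  seeds <- derive_seeds(seed, 4)
  universe <- gen_universe(universe_config(
    n_genes = c(human = 3000, mouse = 3600, fly = 3200),
    mix = c(one_to_one = 0.5, one_to_many = 0.2, many_to_many = 0.1,
            orphan = 0.2),
    seed = seeds[1]))
  deg <- gen_deg_stats(universe, plant_config(
    n_concordant_up = 160, n_concordant_down = 160,
    n_extra = c(human = 250, mouse = 500, fly = 400),
    condition_mix = c(both = 0.4, glia_only = 0.3, neuron_only = 0.3),
    seed = seeds[2]))

  # interaction blocks over planted upregulated human genes: three blocks
  # shared between the glial and neuronal responses, one block private to
  # each condition
  mem <- deg$truth$members
  hum <- mem[mem$species == "human" & mem$direction == "up", , drop = FALSE]
  pool <- function(cond) unique(hum$gene_id[hum$condition %in% cond])
  shared <- pool("both")
  glia_only <- pool("glia_only")
  neuron_only <- pool("neuron_only")
  if (length(shared) < 60 || length(glia_only) < 20 || length(neuron_only) < 20) {
    stop_xc("planted pools too small for the preset's interaction blocks")
  }
  module <- c(shared[1:60], glia_only[1:20], neuron_only[1:20])
  ppi <- gen_ppi_edges(ppi_config(
    n_blocks = 5, block_size = 20, p_within = 0.3, p_between = 0.01,
    background_size = 15884, background_degree = 2,
    module_genes = module, seed = seeds[3]))
  ppi$background <- union(ppi$background, universe$genes$human)
  block_condition <- c(rep("shared", 3), "glia", "neuron")
  ppi$truth$condition <- block_condition[as.integer(ppi$truth$block)]

  behavior <- gen_behavior(
    behavior_config(seed = seeds[4]),
    genotypes = data.frame(
      genotype = c("siHTT", "mod_strong1", "mod_strong2", "mod_weak",
                   "mod_null", "mod_worse"),
      improvement = c(0.4, 0.2, 0.2, 0.1, 0, -0.15),
      stringsAsFactors = FALSE))

  list(universe = universe, deg = deg, ppi = ppi, behavior = behavior,
       network_inputs = list(shared = shared[1:60], glia = glia_only[1:20],
                             neuron = neuron_only[1:20]),
       seed = seed)
}

#' Run the full concordance analysis on a simulated (or assembled) study
#'
#' Executes the pipeline end to end: DEG filtering per species, merged
#' homology graph, per-direction concordance split by fly driver condition,
#' the resampling overlap null, glial and neuronal interaction networks
#' with community detection and size filtering, pairwise cluster
#' comparison, centrality-based candidate ranking, and behavioral screen
#' scoring against the positive control.
#'
#' @param sim a study as returned by [simulate_study()].
#' @param n_overlap_samples resamples for the overlap null (default 1000).
#' @param n_perm permutations per screen genotype (default 999).
#' @param rng_seed seed for the stochastic stages.
#' @param score_screen run the (slower) behavioral scoring stage.
#' @return list with `calls`, `graph`, `condition` (per-direction fly
#'   condition partitions), `overlap_null` (per direction), `networks`,
#'   `partitions`, `comparison`, `ranking`, and `screen`.
#' @export
run_study_pipeline <- function(sim, n_overlap_samples = 1000, n_perm = 999,
                               rng_seed = 1L, score_screen = TRUE) {
  calls <- list(
    human = call_degs_human(sim$deg$human_probes, fc_dialect = "linear"),
    mouse = call_degs_any_contrast(sim$deg$mouse),
    fly_glia = call_degs_any_contrast(sim$deg$fly$glia),
    fly_neuron = call_degs_any_contrast(sim$deg$fly$neuron))

  graph <- build_merged_graph(sim$universe$maps)

  condition <- lapply(setNames(nm = c("up", "down")), function(d) {
    partition_by_fly_condition(
      graph,
      human_degs = deg_gene_set(calls$human, d),
      mouse_degs = deg_gene_set(calls$mouse, d),
      fly_glia_degs = deg_gene_set(calls$fly_glia, d),
      fly_neuron_degs = deg_gene_set(calls$fly_neuron, d),
      direction = d)
  })

  universe_sets <- sim$universe$genes
  seeds <- derive_seeds(rng_seed, 4)
  overlap <- lapply(setNames(nm = c("up", "down")), function(d) {
    overlap_null_test(
      graph, universe_sets,
      deg_sets = list(human = deg_gene_set(calls$human, d),
                      mouse = deg_gene_set(calls$mouse, d),
                      fly = union(deg_gene_set(calls$fly_glia, d),
                                  deg_gene_set(calls$fly_neuron, d))),
      statistic = "human_genes", n_samples = n_overlap_samples,
      rng_seed = seeds[if (d == "up") 1 else 2], direction = d)
  })

  networks <- list(
    glia = build_ppi_network(sim$ppi$edges, restrict_to = condition$up$glia),
    neuron = build_ppi_network(sim$ppi$edges, restrict_to = condition$up$neuron))
  partitions <- lapply(seq_along(networks), function(i) {
    filter_small_clusters(detect_communities(networks[[i]], n_trials = 10,
                                             rng_seed = seeds[3] + i))
  })
  names(partitions) <- names(networks)

  comparison <- pairwise_cluster_similarity(
    partitions$glia, partitions$neuron,
    universe = union(igraph::V(networks$glia)$name,
                     igraph::V(networks$neuron)$name))

  ranking <- centrality_rank_score(partitions$glia,
                                   node_centrality(networks$glia))

  screen <- NULL
  if (score_screen) {
    rec <- sim$behavior$records
    ctrl <- rec[rec$genotype == "posctrl", , drop = FALSE]
    genos <- setdiff(unique(rec$genotype), c("posctrl", "ctrl"))
    screen <- do.call(rbind, lapply(seq_along(genos), function(i) {
      screen_score(rec[rec$genotype == genos[i], , drop = FALSE], ctrl,
                   genotype = genos[i], n_boot = 200, n_perm = n_perm,
                   rng_seed = seeds[4] + i)
    }))
  }

  list(calls = calls, graph = graph, condition = condition,
       overlap_null = overlap, networks = networks, partitions = partitions,
       comparison = comparison, ranking = ranking, screen = screen)
}

#' Fraction of planted concordant components recovered by the pipeline
#'
#' A planted component counts as recovered when every one of its member
#' genes is characterized as concordant in the matching direction by the
#' union-condition concordance fit.
#'
#' @param sim a [simulate_study()] result.
#' @param pipeline the matching [run_study_pipeline()] result.
#' @return list with per-direction recovery fractions and the overall
#'   fraction.
#' @export
planted_recovery <- function(sim, pipeline) {
  mem <- sim$deg$truth$members
  frac <- lapply(setNames(nm = c("up", "down")), function(d) {
    fit <- pipeline$condition[[d]]$fits$union
    md <- mem[mem$direction == d, , drop = FALSE]
    ok <- vapply(split(md, md$component_id), function(cm) {
      all(vapply(seq_len(nrow(cm)), function(i) {
        cm$gene_id[i] %in% fit$concordant_genes[[cm$species[i]]]
      }, logical(1)))
    }, logical(1))
    mean(ok)
  })
  frac$overall <- mean(c(frac$up, frac$down))
  frac
}
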