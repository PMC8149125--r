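#' Configuration for a synthetic tri-species gene universe
#'
#' The homology mix controls the topology of the cross-species map:
#' `one_to_one` components hold one gene per species, `one_to_many`
#' components hold one gene in two species and several in the third
#' (divergence), `many_to_many` components hold two or more genes in every
#' species, and `orphan` genes carry no homology edge at all.
#'
#' @param n_genes genes per species; a scalar or a named vector
#'   (`human`, `mouse`, `fly`).
#' @param mix named fractions (`one_to_one`, `one_to_many`, `many_to_many`,
#'   `orphan`) of each species' genes allocated to each topology; must sum
#'   to 1.
#' @param seed integer seed.
#' @return a `universe_config` list.
#' @export
universe_config <- function(n_genes = 1000,
                            mix = c(one_to_one = 0.5, one_to_many = 0.2,
                                    many_to_many = 0.1, orphan = 0.2),
                            seed = 1L) {
  if (length(n_genes) == 1L) n_genes <- setNames(rep(n_genes, 3), SPECIES_LEVELS)
  n_genes <- n_genes[SPECIES_LEVELS]
  if (any(is.na(n_genes)) || any(n_genes < 1)) {
    stop_xc("n_genes must name all of %s with values >= 1",
            paste(SPECIES_LEVELS, collapse = ", "))
  }
  need <- c("one_to_one", "one_to_many", "many_to_many", "orphan")
  mix <- mix[need]
  if (any(is.na(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop_xc("mix must give non-negative fractions for %s summing to 1",
            paste(need, collapse = ", "))
  }
  structure(list(n_genes = n_genes, mix = mix, seed = as.integer(seed)),
            class = "universe_config")
}

#' Generate a tri-species gene universe with a mixed-topology homology map
#'
#' Deterministic given the config seed. Gene ids are opaque per-species
#' strings. Every non-orphan component is connected across all of its
#' species pairs, and the ground-truth component map is recorded for
#' testing; pipeline stages never read it.
#'
#' @param cfg a [universe_config()].
#' @return list with `genes` (per-species id vectors), `maps` (three
#'   pairwise homology edge data.frames), and `truth` (data.frame
#'   `component_id`, `species`, `gene_id`, `type`).
#' @export
gen_universe <- function(cfg = universe_config()) {
  stopifnot(inherits(cfg, "universe_config"))
  set.seed(cfg$seed)
  prefix <- c(human = "HG", mouse = "MG", fly = "FG")
  pools <- lapply(setNames(nm = SPECIES_LEVELS), function(s) {
    sprintf("%s%05d", prefix[[s]], seq_len(cfg$n_genes[[s]]))
  })
  nmin <- min(cfg$n_genes)
  n11 <- floor(cfg$mix[["one_to_one"]] * nmin)
  n1m <- floor(cfg$mix[["one_to_many"]] * nmin / 2)   # "many" side uses 2 genes
  nmm <- floor(cfg$mix[["many_to_many"]] * nmin / 2)  # 2 genes per species
  # a requested non-zero fraction that rounds to zero components is
  # infeasible at this universe size
  if (cfg$mix[["one_to_one"]] > 0 && n11 == 0) stop_xc("one_to_one fraction infeasible at this n_genes")
  if (cfg$mix[["one_to_many"]] > 0 && n1m == 0) stop_xc("one_to_many fraction infeasible at this n_genes")
  if (cfg$mix[["many_to_many"]] > 0 && nmm == 0) stop_xc("many_to_many fraction infeasible at this n_genes")

  cursor <- setNames(rep(1L, 3), SPECIES_LEVELS)
  take <- function(s, k) {
    i <- cursor[[s]]
    if (i + k - 1L > length(pools[[s]])) stop_xc("gene pool of %s exhausted", s)
    cursor[[s]] <<- i + k
    pools[[s]][i:(i + k - 1L)]
  }

  comp_id <- 0L
  truth <- list()
  edges <- list()
  add_component <- function(members, type) {
    # members: named list species -> gene ids; connect all cross-species pairs
    comp_id <<- comp_id + 1L
    for (s in names(members)) {
      truth[[length(truth) + 1L]] <<- data.frame(
        component_id = comp_id, species = s, gene_id = members[[s]],
        type = type, stringsAsFactors = FALSE)
    }
    sps <- names(members)
    for (i in seq_along(sps)) {
      for (j in seq_along(sps)) {
        if (i < j) {
          grid <- expand.grid(a = members[[sps[i]]], b = members[[sps[j]]],
                              stringsAsFactors = FALSE)
          edges[[length(edges) + 1L]] <<- data.frame(
            species_a = sps[i], gene_a = grid$a,
            species_b = sps[j], gene_b = grid$b,
            score = round(runif(nrow(grid), 1, 15), 2),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  for (i in seq_len(n11)) {
    add_component(list(human = take("human", 1), mouse = take("mouse", 1),
                       fly = take("fly", 1)), "one_to_one")
  }
  for (i in seq_len(n1m)) {
    many <- SPECIES_LEVELS[(i %% 3L) + 1L]   # rotate the diverged species
    m <- list(human = take("human", 1), mouse = take("mouse", 1),
              fly = take("fly", 1))
    m[[many]] <- c(m[[many]], take(many, 1))
    add_component(m, "one_to_many")
  }
  for (i in seq_len(nmm)) {
    add_component(list(human = take("human", 2), mouse = take("mouse", 2),
                       fly = take("fly", 2)), "many_to_many")
  }
  # every remaining gene is an orphan
  for (s in SPECIES_LEVELS) {
    if (cursor[[s]] <= length(pools[[s]])) {
      left <- pools[[s]][cursor[[s]]:length(pools[[s]])]
      comp_id <- comp_id + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        component_id = seq(comp_id, comp_id + length(left) - 1L),
        species = s, gene_id = left, type = "orphan", stringsAsFactors = FALSE)
      comp_id <- comp_id + length(left) - 1L
    }
  }
  truth <- do.call(rbind, truth)
  maps <- list()
  if (length(edges)) {
    all_edges <- do.call(rbind, edges)
    pair_key <- function(sa, sb) paste(pmin(sa, sb), pmax(sa, sb), sep = "-")
    maps <- unname(split(all_edges, pair_key(all_edges$species_a,
                                             all_edges$species_b)))
  }
  list(genes = pools, maps = maps, truth = truth)
}

#' Configuration for planted differential-expression signal
#'
#' @param n_concordant_up,n_concordant_down numbers of tri-species homology
#'   components planted as concordantly up-/down-regulated.
#' @param n_extra per-species, per-direction count of additional planted
#'   DEGs that do not form concordant components (species-private signal).
#' @param p_signal_max planted p-values are drawn `Uniform(0, p_signal_max)`;
#'   only the rank/threshold structure of the summary statistics matters
#'   downstream, so a parametric alternative is not modelled.
#' @param lfc_range magnitude range of planted log2 fold-changes.
#' @param null_lfc_sd SD of null log2 fold-changes (symmetric around 0).
#' @param n_timepoints fly timepoints per driver and model.
#' @param models fly disease-model labels (two transgenes by default).
#' @param condition_mix fractions of planted components assigned to the
#'   `both`, `glia_only` and `neuron_only` fly driver conditions.
#' @param discordant_fraction fraction of planted components given an
#'   inconsistent sign in one species (exercises conflict handling; 0 by
#'   default so planted components are concordant by construction).
#' @param n_probes_max human genes carry 1..n_probes_max microarray probes.
#' @param seed integer seed.
#' @return a `plant_config` list.
#' @export
plant_config <- function(n_concordant_up = 40, n_concordant_down = 40,
                         n_extra = c(human = 100, mouse = 150, fly = 150),
                         p_signal_max = 1e-4, lfc_range = c(0.45, 2.5),
                         null_lfc_sd = 0.35, n_timepoints = 3,
                         models = c("NT", "FL"),
                         condition_mix = c(both = 0.4, glia_only = 0.3,
                                           neuron_only = 0.3),
                         discordant_fraction = 0, n_probes_max = 2,
                         seed = 1L) {
  if (abs(sum(condition_mix) - 1) > 1e-9) stop_xc("condition_mix must sum to 1")
  structure(as.list(environment()), class = "plant_config")
}

rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)

#' Generate differential-expression summary tables with planted signal
#'
#' Plants `n_concordant_up + n_concordant_down` tri-species homology
#' components as concordant DEGs: every member gene receives a small
#' p-value (at one or more contrasts) with a direction shared across the
#' component, so concordance holds by construction. All other genes are
#' nulls with uniform p-values and sign-symmetric fold-changes. Fly
#' components are assigned to driver conditions (`both`, `glia_only`,
#' `neuron_only`); a `glia_only` component's fly genes are significant only
#' under the glial driver.
#'
#' Human output is a probe-level table (signed linear fold-changes, 1-2
#' probes per gene) for the microarray-style filter; mouse output is a
#' single continuous-trait contrast; fly output is one table per driver
#' covering `models x n_timepoints` contrasts.
#'
#' @param universe output of [gen_universe()].
#' @param plant a [plant_config()].
#' @return list with `human_probes`, `mouse`, `fly` (list `glia`, `neuron`),
#'   and `truth` (planted components with direction and fly condition, plus
#'   per-species planted gene tables).
#' @export
gen_deg_stats <- function(universe, plant = plant_config()) {
  stopifnot(inherits(plant, "plant_config"))
  set.seed(plant$seed)
  tr <- universe$truth
  tri <- unlist(lapply(split(tr$species, tr$component_id),
                       function(s) length(unique(s)) == 3L))
  tri_ids <- as.integer(names(tri))[tri]
  n_plant <- plant$n_concordant_up + plant$n_concordant_down
  if (n_plant > length(tri_ids)) {
    stop_xc("cannot plant %d components: only %d tri-species components exist",
            n_plant, length(tri_ids))
  }
  picked <- sample(tri_ids, n_plant)
  comp_dir <- setNames(rep(c("up", "down"),
                           c(plant$n_concordant_up, plant$n_concordant_down)),
                       picked)
  conds <- names(plant$condition_mix)
  # conditions are allocated deterministically (within each direction) so
  # the planted condition counts are fixed study parameters, not draws
  alloc_conditions <- function(n) {
    cnt <- floor(n * plant$condition_mix)
    rem <- n - sum(cnt)
    if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1
    sample(rep(conds, cnt))
  }
  comp_cond <- setNames(c(alloc_conditions(plant$n_concordant_up),
                          alloc_conditions(plant$n_concordant_down)), picked)
  discord <- setNames(runif(n_plant) < plant$discordant_fraction, picked)

  planted <- tr[tr$component_id %in% picked, , drop = FALSE]
  planted$direction <- comp_dir[as.character(planted$component_id)]
  planted$condition <- comp_cond[as.character(planted$component_id)]
  # a discordant component flips the sign of its mouse genes
  flip <- discord[as.character(planted$component_id)] & planted$species == "mouse"
  planted$direction[flip] <- ifelse(planted$direction[flip] == "up", "down", "up")

  plant_gene_table <- function(species) {
    sub <- planted[planted$species == species,
                   c("gene_id", "direction", "condition")]
    extras_n <- plant$n_extra[[species]] %||% 0
    if (extras_n > 0) {
      free <- setdiff(universe$genes[[species]], sub$gene_id)
      ex <- sample(free, min(2 * extras_n, length(free)))
      sub <- rbind(sub, data.frame(
        gene_id = ex,
        direction = rep(c("up", "down"), length.out = length(ex)),
        condition = sample(conds, length(ex), replace = TRUE,
                           prob = plant$condition_mix),
        stringsAsFactors = FALSE))
    }
    sub
  }
  sig <- lapply(setNames(nm = SPECIES_LEVELS), plant_gene_table)

  sig_lfc <- function(n, dir) {
    ifelse(dir == "up", 1, -1) * runif(n, plant$lfc_range[1], plant$lfc_range[2])
  }

  # --- human: probe-level, signed linear fold-change ---
  hg <- universe$genes$human
  n_probes <- sample.int(plant$n_probes_max, length(hg), replace = TRUE)
  probes <- data.frame(
    probe_id = sprintf("probe%06d", seq_len(sum(n_probes))),
    gene_id = rep(hg, n_probes), stringsAsFactors = FALSE)
  probes$p_value <- runif(nrow(probes))
  probes$fold_change <- rsign(nrow(probes)) * runif(nrow(probes), 1.0, 1.6)
  hs <- sig$human
  first_probe <- match(hs$gene_id, probes$gene_id)  # one probe carries signal
  probes$p_value[first_probe] <- runif(nrow(hs), 0, plant$p_signal_max)
  probes$fold_change[first_probe] <-
    ifelse(hs$direction == "up", 1, -1) * runif(nrow(hs), 1.35, 3)

  # --- mouse: one continuous-trait contrast ---
  mg <- universe$genes$mouse
  mouse <- data.frame(gene_id = mg, species = "mouse",
                      contrast_label = "continuous-Q",
                      log2fc = rnorm(length(mg), 0, plant$null_lfc_sd),
                      p_value = runif(length(mg)), stringsAsFactors = FALSE)
  ms <- sig$mouse
  mi <- match(ms$gene_id, mouse$gene_id)
  mouse$p_value[mi] <- runif(nrow(ms), 0, plant$p_signal_max)
  mouse$log2fc[mi] <- sig_lfc(nrow(ms), ms$direction)

  # --- fly: per driver, models x timepoints contrasts ---
  fg <- universe$genes$fly
  contrasts <- as.vector(outer(plant$models, seq_len(plant$n_timepoints),
                               function(m, t) paste0(m, "_t", t)))
  fly_table <- function(driver) {
    df <- expand.grid(gene_id = fg, contrast_label = contrasts,
                      stringsAsFactors = FALSE)
    df$species <- "fly"
    df$log2fc <- rnorm(nrow(df), 0, plant$null_lfc_sd)
    df$p_value <- runif(nrow(df))
    fs <- sig$fly
    active <- fs$condition == "both" |
      (driver == "glia" & fs$condition == "glia_only") |
      (driver == "neuron" & fs$condition == "neuron_only")
    fs <- fs[active, , drop = FALSE]
    if (nrow(fs)) {
      # each planted fly gene is significant at two of the contrasts
      for (ci in 1:2) {
        pick <- paste0(fs$gene_id, "\r", sample(contrasts, nrow(fs), replace = TRUE))
        rows <- match(pick, paste0(df$gene_id, "\r", df$contrast_label))
        df$p_value[rows] <- runif(nrow(fs), 0, plant$p_signal_max)
        df$log2fc[rows] <- sig_lfc(nrow(fs), fs$direction)
      }
    }
    df[, c("gene_id", "species", "contrast_label", "log2fc", "p_value")]
  }
  fly <- list(glia = fly_table("glia"), neuron = fly_table("neuron"))

  list(human_probes = probes, mouse = mouse, fly = fly,
       truth = list(components = unique(planted[, c("component_id", "direction",
                                                    "condition")]),
                    members = planted, signal_genes = sig))
}

#' Configuration for a planted-partition interaction network
#'
#' @param n_blocks,block_size planted community count and size.
#' @param p_within,p_between within-block and between-block edge
#'   probabilities among module genes.
#' @param background_size total proteome size (module plus background).
#' @param background_degree expected noise-edge degree of background nodes.
#' @param w_true,w_spurious weight ranges (uniform) for true within-block
#'   edges and for spurious edges; true edges mostly clear the 0.7
#'   confidence threshold, spurious edges mostly do not.
#' @param n_small_blocks,small_block_size optional planted sub-threshold
#'   blocks (complete subgraphs smaller than the size filter) used to
#'   exercise cluster-size filtering.
#' @param module_genes optional explicit node ids for the module; generated
#'   protein ids otherwise.
#' @param seed integer seed.
#' @return a `ppi_config` list.
#' @export
ppi_config <- function(n_blocks = 5, block_size = 20, p_within = 0.3,
                       p_between = 0.01, background_size = 2000,
                       background_degree = 2,
                       w_true = c(0.75, 0.999), w_spurious = c(0.2, 0.8),
                       n_small_blocks = 0, small_block_size = 3,
                       module_genes = NULL, seed = 1L) {
  for (p in c(p_within, p_between)) check_prob(p, "edge probability")
  structure(as.list(environment()), class = "ppi_config")
}

rand_pairs <- function(ids, m) {
  if (m <= 0 || length(ids) < 2) {
    return(data.frame(node_a = character(), node_b = character()))
  }
  a <- sample(ids, m, replace = TRUE)
  b <- sample(ids, m, replace = TRUE)
  keep <- a != b
  df <- unique(data.frame(node_a = pmin(a[keep], b[keep]),
                          node_b = pmax(a[keep], b[keep]),
                          stringsAsFactors = FALSE))
  df
}

#' Generate a weighted interaction edge table with planted communities
#'
#' Builds a planted-partition graph over the module genes (dense,
#' high-confidence within blocks; sparse, low-confidence between), embeds it
#' in a larger weakly connected background proteome, and records the
#' ground-truth block assignment.
#'
#' @param cfg a [ppi_config()].
#' @return list with `edges` (`node_a`, `node_b`, `weight` in \[0,1\]),
#'   `background` (all node ids), `module` (module node ids), and `truth`
#'   (data.frame `node`, `block`; small blocks get labels `"small<k>"`).
#' @export
gen_ppi_edges <- function(cfg = ppi_config()) {
  stopifnot(inherits(cfg, "ppi_config"))
  set.seed(cfg$seed)
  n_mod <- cfg$n_blocks * cfg$block_size +
    cfg$n_small_blocks * cfg$small_block_size
  mod <- cfg$module_genes %||% sprintf("PROT%05d", seq_len(n_mod))
  if (length(mod) < n_mod) stop_xc("need %d module genes, got %d", n_mod, length(mod))
  mod <- mod[seq_len(n_mod)]
  blocks <- rep(as.character(seq_len(cfg$n_blocks)), each = cfg$block_size)
  if (cfg$n_small_blocks > 0) {
    blocks <- c(blocks, rep(paste0("small", seq_len(cfg$n_small_blocks)),
                            each = cfg$small_block_size))
  }
  n_bg <- cfg$background_size - n_mod
  bg <- if (n_bg > 0) sprintf("BPROT%05d", seq_len(n_bg)) else character()
  all_nodes <- c(mod, bg)

  w_true <- function(n) runif(n, cfg$w_true[1], cfg$w_true[2])
  w_sp <- function(n) runif(n, cfg$w_spurious[1], cfg$w_spurious[2])

  edge_list <- list()
  for (bl in unique(blocks)) {
    ids <- mod[blocks == bl]
    pairs <- t(utils::combn(ids, 2))
    keep <- if (startsWith(bl, "small")) rep(TRUE, nrow(pairs)) else
      runif(nrow(pairs)) < cfg$p_within
    if (any(keep)) {
      edge_list[[length(edge_list) + 1L]] <- data.frame(
        node_a = pairs[keep, 1], node_b = pairs[keep, 2],
        weight = w_true(sum(keep)), stringsAsFactors = FALSE)
    }
  }
  # between-block spurious edges among module genes
  n_between <- round(cfg$p_between * choose(length(mod), 2))
  btw <- rand_pairs(mod, n_between)
  if (nrow(btw)) {
    same_block <- blocks[match(btw$node_a, mod)] == blocks[match(btw$node_b, mod)]
    btw <- btw[!same_block, , drop = FALSE]
    if (nrow(btw)) {
      btw$weight <- w_sp(nrow(btw))
      edge_list[[length(edge_list) + 1L]] <- btw
    }
  }
  # background noise edges over the whole proteome
  n_noise <- round(cfg$background_degree * length(all_nodes) / 2)
  noise <- rand_pairs(all_nodes, n_noise)
  if (nrow(noise)) {
    noise$weight <- w_sp(nrow(noise))
    edge_list[[length(edge_list) + 1L]] <- noise
  }
  edges <- do.call(rbind, edge_list)
  edges <- edges[!duplicated(edges[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, background = all_nodes, module = mod,
       truth = data.frame(node = mod, block = blocks, stringsAsFactors = FALSE))
}

#' Configuration for synthetic climbing trajectories
#'
#' Climbing speed declines linearly with age; disease-model flies decline
#' much faster than healthy controls. Speeds are vial means in mm/s. A
#' baseline of 20 mm/s with a decline of 1.5 mm/s/day takes the positive
#' control from ~18.5 to ~6.5 mm/s over a 9-day trial, the rapid (but still
#' age-dependent) collapse typical of pan-glial disease models; healthy
#' controls lose speed an order of magnitude more slowly.
#'
#' @param s0 baseline speed at day 0 (mm/s).
#' @param decline_pos daily speed loss of the positive control (mm/s/day).
#' @param decline_healthy daily speed loss of healthy controls (mm/s/day).
#' @param noise_sd replicate (vial) noise SD (mm/s).
#' @param n_replicates vials per genotype per day.
#' @param n_days trial length in days.
#' @param n_animals animals per vial (metadata only).
#' @param seed integer seed.
#' @return a `behavior_config` list.
#' @export
behavior_config <- function(s0 = 20, decline_pos = 1.5, decline_healthy = 0.35,
                            noise_sd = 1, n_replicates = 6, n_days = 9,
                            n_animals = 10, seed = 1L) {
  if (s0 <= 0) stop_xc("s0 must be positive")
  structure(as.list(environment()), class = "behavior_config")
}

#' Generate longitudinal climbing-speed records with planted effects
#'
#' Each modifier genotype's mean trajectory is a multiplicative rescaling of
#' the positive-control trajectory: `mu_g(d) = (1 + improvement_g) *
#' max(0, s0 - decline_pos * d)`, so the planted `improvement` equals the
#' analytic percent improvement (divided by 100) under the day-averaged
#' relative-difference score. Replicate speeds add Gaussian noise and are
#' floored at 0. A healthy control genotype (`"ctrl"`) with its own slow
#' decline and the positive control (`"posctrl"`) are always emitted.
#'
#' @param cfg a [behavior_config()].
#' @param genotypes data.frame with columns `genotype` and `improvement`
#'   (fractional, e.g. 0.2 for +20%); may be empty.
#' @return list with `records` (data.frame `genotype`, `age_day`,
#'   `replicate_id`, `speed`, `n_animals`) and `truth` (the genotype table
#'   including the two controls).
#' @export
gen_behavior <- function(cfg = behavior_config(),
                         genotypes = data.frame(genotype = character(),
                                                improvement = numeric())) {
  stopifnot(inherits(cfg, "behavior_config"))
  set.seed(cfg$seed)
  gt <- rbind(data.frame(genotype = c("ctrl", "posctrl"),
                         improvement = c(NA_real_, 0),
                         stringsAsFactors = FALSE),
              genotypes[, c("genotype", "improvement")])
  days <- seq_len(cfg$n_days)
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt$genotype[i]
    mu <- if (g == "ctrl") {
      pmax(0, cfg$s0 - cfg$decline_healthy * days)
    } else {
      (1 + gt$improvement[i]) * pmax(0, cfg$s0 - cfg$decline_pos * days)
    }
    df <- expand.grid(age_day = days, replicate_id = sprintf("r%02d", seq_len(cfg$n_replicates)),
                      stringsAsFactors = FALSE)
    df$genotype <- g
    df$speed <- pmax(0, mu[df$age_day] + rnorm(nrow(df), 0, cfg$noise_sd))
    df$n_animals <- cfg$n_animals
    df[, c("genotype", "age_day", "replicate_id", "speed", "n_animals")]
  })
  list(records = do.call(rbind, rows), truth = gt)
}
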