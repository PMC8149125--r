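#' Build the merged tri-species homology graph
#'
#' Each pairwise homology map (fly-human, fly-mouse, mouse-human) is an
#' undirected bipartite graph whose nodes are species-tagged genes and whose
#' edges denote homology. Merging the maps yields one simple undirected graph
#' in which evolutionary divergence and convergence appear as components with
#' several genes per species; no one-to-one mapping is imposed.
#'
#' @param maps list of data.frames, each with columns `species_a`, `gene_a`,
#'   `species_b`, `gene_b` and optionally `score`. Duplicate edges collapse.
#' @param min_score optional score floor; edges with `score < min_score` are
#'   dropped (edges without a score are kept). Default 0 keeps everything,
#'   including low-confidence ortholog calls.
#' @return An igraph object with vertex attributes `species` and `gene`;
#'   vertex names are `species:gene_id`.
#' @examples
#' m1 <- data.frame(species_a = "human", gene_a = "H1",
#'                  species_b = "mouse", gene_b = "M1")
#' m2 <- data.frame(species_a = "mouse", gene_a = "M1",
#'                  species_b = "fly", gene_b = "F1")
#' g <- build_merged_graph(list(m1, m2))
#' igraph::vcount(g)  # 3
#' @export
build_merged_graph <- function(maps, min_score = 0) {
  if (!length(maps)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "species", value = character())
    g <- igraph::set_vertex_attr(g, "gene", value = character())
    return(g)
  }
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  edges <- do.call(rbind, lapply(maps, function(m) {
    miss <- setdiff(need, names(m))
    if (length(miss)) stop_xc("homology map lacks column(s): %s", paste(miss, collapse = ", "))
    data.frame(species_a = as.character(m$species_a), gene_a = as.character(m$gene_a),
               species_b = as.character(m$species_b), gene_b = as.character(m$gene_b),
               score = if (is.null(m$score)) NA_real_ else as.numeric(m$score),
               stringsAsFactors = FALSE)
  }))
  check_species(c(edges$species_a, edges$species_b))
  same <- which(edges$species_a == edges$species_b)
  if (length(same)) {
    stop_xc("homology edge joins two genes of the same species: %s",
            paste(sprintf("%s:%s-%s", edges$species_a[same], edges$gene_a[same],
                          edges$gene_b[same])[seq_len(min(5L, length(same)))],
                  collapse = ", "))
  }
  if (min_score > 0) {
    edges <- edges[is.na(edges$score) | edges$score >= min_score, , drop = FALSE]
  }
  from <- paste(edges$species_a, edges$gene_a, sep = ":")
  to <- paste(edges$species_b, edges$gene_b, sep = ":")
  verts <- unique(data.frame(
    name = c(from, to),
    species = c(edges$species_a, edges$species_b),
    gene = c(edges$gene_a, edges$gene_b),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE, vertices = verts)
  igraph::simplify(g)
}

species_vertices <- function(graph, deg_sets) {
  check_species(names(deg_sets), "deg_sets name")
  sp <- igraph::V(graph)$species
  gn <- igraph::V(graph)$gene
  keep <- rep(FALSE, length(sp))
  for (s in names(deg_sets)) {
    keep <- keep | (sp == s & gn %in% deg_sets[[s]])
  }
  which(keep)
}

#' Concordance calls from the DEG-induced homology subgraph
#'
#' Induces the merged homology graph on the direction-matched DEG sets of
#' each species and computes connected components. A component whose members
#' cover every species in `required_species` is concordant, and all of its
#' genes are characterized as concordant.
#'
#' @param graph merged homology graph from [build_merged_graph()].
#' @param deg_sets named list (`human`, `mouse`, `fly`, any subset) of gene-id
#'   vectors, all for one direction of change.
#' @param direction `"up"` or `"down"`; components are computed per direction
#'   independently and the label is carried into the output.
#' @param required_species species that must be present for a component to be
#'   concordant; default all three.
#' @return An object of class `concordance`: list with `components` (a
#'   data.frame: `component_id`, `species`, `gene_id`, `direction`,
#'   `concordant`), `n_components`, `n_concordant_components`,
#'   `concordant_genes` (named list of per-species gene vectors, each gene
#'   counted once), and `counts` (named integer vector of those set sizes).
#' @export
concordant_components <- function(graph, deg_sets,
                                  direction = c("up", "down"),
                                  required_species = SPECIES_LEVELS) {
  direction <- match.arg(direction)
  check_species(required_species, "required_species")
  vids <- species_vertices(graph, deg_sets)
  empty <- structure(list(
    components = data.frame(component_id = integer(), species = character(),
                            gene_id = character(), direction = character(),
                            concordant = logical(), stringsAsFactors = FALSE),
    n_components = 0L, n_concordant_components = 0L,
    concordant_genes = setNames(
      lapply(SPECIES_LEVELS, function(s) character()), SPECIES_LEVELS),
    counts = setNames(integer(length(SPECIES_LEVELS)), SPECIES_LEVELS),
    direction = direction, required_species = required_species),
    class = "concordance")
  if (!length(vids)) return(empty)

  sub <- igraph::induced_subgraph(graph, vids)
  comp <- igraph::components(sub)
  sp <- igraph::V(sub)$species
  gn <- igraph::V(sub)$gene
  mem <- comp$membership

  conc_ids <- Reduce(intersect,
                     lapply(required_species, function(s) unique(mem[sp == s])))
  df <- data.frame(component_id = as.integer(mem), species = sp, gene_id = gn,
                   direction = direction, concordant = mem %in% conc_ids,
                   stringsAsFactors = FALSE)
  df <- df[order(df$component_id, df$species, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  cg <- setNames(lapply(SPECIES_LEVELS, function(s) {
    sort(unique(df$gene_id[df$concordant & df$species == s]))
  }), SPECIES_LEVELS)
  structure(list(components = df, n_components = comp$no,
                 n_concordant_components = length(conc_ids),
                 concordant_genes = cg,
                 counts = vapply(cg, length, integer(1)),
                 direction = direction, required_species = required_species),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance (%s-regulated; requires %s)\n", x$direction,
              paste(x$required_species, collapse = "+")))
  cat(sprintf("  %d induced components, %d concordant\n",
              x$n_components, x$n_concordant_components))
  cat("  concordant genes:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Concordant overlaps split by the fly driver condition
#'
#' Recomputes tri-species concordance three times, with the fly DEG set taken
#' as the glia-condition set, the neuron-condition set, and their union, and
#' reports the human-gene concordant sets for the glia condition, the neuron
#' condition, and their intersection ("both"), plus the condition-exclusive
#' remainders.
#'
#' @param graph merged homology graph.
#' @param human_degs,mouse_degs human and mouse gene sets (one direction).
#' @param fly_glia_degs,fly_neuron_degs fly gene sets for the glial and
#'   neuronal driver conditions (same direction).
#' @param direction `"up"` or `"down"`.
#' @param required_species species coverage required for concordance.
#' @return list with human gene sets `glia`, `neuron`, `both`, `glia_only`,
#'   `neuron_only`, `union`, a `counts` vector, and the three underlying
#'   `concordance` objects in `$fits`.
#' @export
partition_by_fly_condition <- function(graph, human_degs, mouse_degs,
                                       fly_glia_degs, fly_neuron_degs,
                                       direction = c("up", "down"),
                                       required_species = SPECIES_LEVELS) {
  direction <- match.arg(direction)
  run <- function(fly) {
    concordant_components(graph,
                          list(human = human_degs, mouse = mouse_degs, fly = fly),
                          direction = direction,
                          required_species = required_species)
  }
  f_glia <- run(fly_glia_degs)
  f_neuron <- run(fly_neuron_degs)
  f_union <- run(union(fly_glia_degs, fly_neuron_degs))
  glia <- f_glia$concordant_genes$human
  neuron <- f_neuron$concordant_genes$human
  both <- intersect(glia, neuron)
  out <- list(glia = glia, neuron = neuron, both = both,
              glia_only = setdiff(glia, both),
              neuron_only = setdiff(neuron, both),
              union = f_union$concordant_genes$human,
              fits = list(glia = f_glia, neuron = f_neuron, union = f_union))
  out$counts <- vapply(out[c("glia", "neuron", "both", "glia_only",
                             "neuron_only", "union")], length, integer(1))
  out
}

#' Genes whose homology component lacks a target species
#'
#' Evaluated on the complete merged graph, not the DEG-induced subgraph: a
#' gene has no ortholog in `target_species` when its full homology component
#' (or isolation from the graph entirely) contains no node of that species.
#'
#' @param gene_set gene ids in `species`' namespace.
#' @param species species of `gene_set`.
#' @param graph merged homology graph.
#' @param target_species the species whose orthologs are sought.
#' @return the subset of `gene_set` without any `target_species` ortholog.
#' @export
genes_without_ortholog <- function(gene_set, species, graph, target_species) {
  check_species(species)
  check_species(target_species, "target_species")
  sp <- igraph::V(graph)$species
  gn <- igraph::V(graph)$gene
  idx <- match(gene_set, gn[sp == species])
  vid <- which(sp == species)[idx]
  comp <- igraph::components(graph)
  mem <- comp$membership
  has_target <- unique(mem[sp == target_species])
  absent <- is.na(vid)                      # not in the graph at all
  lacks <- !absent & !(mem[vid] %in% has_target)
  gene_set[absent | lacks]
}
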