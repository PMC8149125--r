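# Independent brute-force oracles. These re-derive expected values from
# first principles (definition-level implementations) and are deliberately
# kept free of the package's own code paths.

# Benjamini-Hochberg by the textbook definition: adj_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Connected components by depth-first search over an explicit adjacency list.
# Nodes are "species:gene" strings; edges a 2-column character matrix.
components_oracle <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (a %in% nodes && b %in% nodes) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    stack <- start
    comp <- character()
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Tri-species concordance from the component oracle: induce on the DEG node
# set, take components, and mark those covering all required species.
concordance_oracle <- function(edge_df, deg_sets, required = c("human", "mouse", "fly")) {
  nodes <- unlist(lapply(names(deg_sets), function(s) {
    paste(s, deg_sets[[s]], sep = ":")
  }), use.names = FALSE)
  all_nodes <- unique(c(paste(edge_df$species_a, edge_df$gene_a, sep = ":"),
                        paste(edge_df$species_b, edge_df$gene_b, sep = ":")))
  nodes <- intersect(nodes, all_nodes)   # genes absent from the map have no node
  edges <- cbind(paste(edge_df$species_a, edge_df$gene_a, sep = ":"),
                 paste(edge_df$species_b, edge_df$gene_b, sep = ":"))
  comps <- components_oracle(nodes, edges)
  spec_of <- function(x) sub(":.*$", "", x)
  conc <- vapply(comps, function(cp) all(required %in% spec_of(cp)), logical(1))
  list(components = comps, concordant = conc,
       concordant_nodes = sort(as.character(unlist(comps[conc]))),
       human_genes = sum(spec_of(unlist(comps[conc])) == "human"))
}

# Random tri-species universe (edge list form) for oracle comparisons.
random_universe_edges <- function(n_per_species, n_edges) {
  pools <- list(human = sprintf("h%d", seq_len(n_per_species)),
                mouse = sprintf("m%d", seq_len(n_per_species)),
                fly = sprintf("f%d", seq_len(n_per_species)))
  pairs <- list(c("human", "mouse"), c("human", "fly"), c("mouse", "fly"))
  rows <- lapply(seq_len(n_edges), function(i) {
    pr <- pairs[[sample.int(3, 1)]]
    data.frame(species_a = pr[1], gene_a = sample(pools[[pr[1]]], 1),
               species_b = pr[2], gene_b = sample(pools[[pr[2]]], 1),
               stringsAsFactors = FALSE)
  })
  list(pools = pools, edges = unique(do.call(rbind, rows)))
}

# Exact betweenness by exhaustive enumeration of all simple paths between
# every unordered pair, crediting interior nodes of minimum-length paths.
betweenness_oracle <- function(adj_matrix) {
  n <- nrow(adj_matrix)
  btw <- numeric(n)
  all_paths <- function(s, t, visited, path) {
    if (s == t) return(list(path))
    out <- list()
    for (v in which(adj_matrix[s, ] == 1)) {
      if (!visited[v]) {
        visited2 <- visited; visited2[v] <- TRUE
        out <- c(out, all_paths(v, t, visited2, c(path, v)))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      visited <- rep(FALSE, n); visited[s] <- TRUE
      paths <- all_paths(s, t, visited, s)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(shortest)
      }
    }
  }
  btw
}

# Upper-tail hypergeometric by direct summation of the pmf via choose().
hyper_tail_oracle <- function(overlap, size_a, size_b, universe) {
  ks <- overlap:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# Kolmogorov-Smirnov distance of a sample from Uniform(0, 1).
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - (seq_len(n) - 1) / n), abs(p - seq_len(n) / n))
}
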