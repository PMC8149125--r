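#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, size_a, size_b)`:
#' the chance that two random subsets of the stated sizes share at least
#' `overlap` members.
#'
#' @param overlap observed overlap count.
#' @param size_a,size_b sizes of the two sets.
#' @param universe size of the common universe.
#' @param log_p return the natural-log probability (stable far in the tail).
#' @return the tail probability (or its log).
#' @examples
#' hypergeometric_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometric_upper_tail <- function(overlap, size_a, size_b, universe,
                                      log_p = FALSE) {
  if (any(c(overlap, size_a, size_b, universe) < 0) ||
      overlap > min(size_a, size_b) || size_a > universe || size_b > universe) {
    stop_xc("inconsistent counts: need overlap <= min(size_a, size_b) and sizes <= universe")
  }
  stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                lower.tail = FALSE, log.p = log_p)
}

#' Pairwise hypergeometric comparison of two clusterings
#'
#' Every cluster of partition A is tested against every cluster of partition
#' B for greater-than-chance shared membership. A pair matches when its raw
#' upper-tail hypergeometric p is below `alpha`; the conventional stringent
#' cutoff of 1e-5 substitutes for multiplicity adjustment, so no correction
#' is applied to the matrix.
#'
#' @param partition_a,partition_b `community_partition` objects (or named
#'   assignment vectors); normally already size-filtered.
#' @param universe node universe for the test. The union of the two
#'   partitions' node sets is the smallest defensible choice and the usual
#'   one here; pass a wider background to be more conservative.
#' @param alpha match threshold on the raw p, default 1e-5.
#' @return object of class `cluster_match`: list with `p_matrix`
#'   (clusters-of-A x clusters-of-B), `matches` (data.frame `cluster_a`,
#'   `cluster_b`, `overlap`, `p`, `matched`), `alpha`, `universe_size`.
#' @export
pairwise_cluster_similarity <- function(partition_a, partition_b, universe,
                                        alpha = 1e-5) {
  as_assign <- function(p) {
    if (inherits(p, "community_partition")) p$assignment else p
  }
  a <- as_assign(partition_a)
  b <- as_assign(partition_b)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_xc("universe must be non-empty")
  ca <- split(names(a)[!is.na(a)], a[!is.na(a)])
  cb <- split(names(b)[!is.na(b)], b[!is.na(b)])
  N <- length(universe)
  p_matrix <- matrix(NA_real_, length(ca), length(cb),
                     dimnames = list(names(ca), names(cb)))
  rows <- vector("list", length(ca) * length(cb))
  i <- 0L
  for (la in names(ca)) {
    for (lb in names(cb)) {
      ov <- length(intersect(ca[[la]], cb[[lb]]))
      p <- hypergeometric_upper_tail(ov, length(ca[[la]]), length(cb[[lb]]), N)
      p_matrix[la, lb] <- p
      i <- i + 1L
      rows[[i]] <- data.frame(cluster_a = la, cluster_b = lb, overlap = ov,
                              p = p, matched = p < alpha,
                              stringsAsFactors = FALSE)
    }
  }
  matches <- if (i) do.call(rbind, rows[seq_len(i)]) else
    data.frame(cluster_a = character(), cluster_b = character(),
               overlap = integer(), p = numeric(), matched = logical())
  structure(list(p_matrix = p_matrix, matches = matches, alpha = alpha,
                 universe_size = N),
            class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("Pairwise cluster comparison: %d x %d clusters, universe %d, alpha %g\n",
              nrow(x$p_matrix), ncol(x$p_matrix), x$universe_size, x$alpha))
  cat(sprintf("  %d matched pairs\n", sum(x$matches$matched)))
  invisible(x)
}

#' Clusters of A with no match in B
#'
#' @param match a `cluster_match` from [pairwise_cluster_similarity()].
#' @return character labels of A-clusters that matched no B-cluster.
#' @export
unmatched_clusters <- function(match) {
  stopifnot(inherits(match, "cluster_match"))
  hit <- rowSums(match$p_matrix < match$alpha) > 0
  rownames(match$p_matrix)[!hit]
}

#' One-sided Fisher enrichment of a cluster in an external gene list
#'
#' Builds the 2x2 table (in both / cluster only / external only / neither)
#' over `universe` and reports the one-sided (enrichment) exact p, which for
#' this table equals [hypergeometric_upper_tail()] on the same counts, plus
#' the unconditional sample odds ratio. A Haldane-Anscombe 0.5 correction is
#' applied to the odds ratio for display only when a cell is zero; the p
#' never uses it.
#'
#' @param cluster_genes,external_list gene sets; both must be subsets of
#'   `universe`.
#' @param universe the gene universe.
#' @return object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `odds_ratio`, `p_value`, `universe_size`.
#' @export
fisher_enrichment <- function(cluster_genes, external_list, universe) {
  universe <- unique(as.character(universe))
  cluster_genes <- unique(as.character(cluster_genes))
  external_list <- unique(as.character(external_list))
  out_c <- setdiff(cluster_genes, universe)
  out_e <- setdiff(external_list, universe)
  if (length(out_c) || length(out_e)) {
    stop_xc("genes outside the universe: %s",
            paste(head(c(out_c, out_e), 10L), collapse = ", "))
  }
  a <- length(intersect(cluster_genes, external_list))
  b <- length(cluster_genes) - a
  cc <- length(external_list) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("in_cluster", "not_cluster"),
                                c("in_external", "not_external")))
  p <- hypergeometric_upper_tail(a, length(cluster_genes),
                                 length(external_list), length(universe))
  num <- a * d
  den <- b * cc
  or <- if (den > 0) num / den else if (num > 0) Inf else
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 universe_size = length(universe)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher enrichment (one-sided): OR = %.3g, p = %.3g, universe %d\n",
              x$odds_ratio, x$p_value, x$universe_size))
  print(x$table)
  invisible(x)
}

#' Direction-matched overlap of concordant sets with external human DEG lists
#'
#' Intersects the human-projected concordant gene sets (per direction) with
#' an external human DEG list of the same direction, e.g. glial-progenitor
#' differential expression, and reports membership and counts.
#'
#' @param concordant_sets named list with elements `up` and/or `down`:
#'   human-gene vectors from the concordance analysis.
#' @param external_degs either a `deg_calls` data.frame (human) or a named
#'   list with `up`/`down` gene vectors.
#' @return named list per direction: list with `genes` and `count`.
#' @export
cross_species_overlap <- function(concordant_sets, external_degs) {
  if (is.data.frame(external_degs)) {
    external_degs <- list(up = deg_gene_set(external_degs, "up"),
                          down = deg_gene_set(external_degs, "down"))
  }
  dirs <- intersect(names(concordant_sets), c("up", "down"))
  if (!length(dirs)) stop_xc("concordant_sets needs elements named 'up' and/or 'down'")
  if (!all(dirs %in% names(external_degs))) {
    stop_xc("direction mismatch: external list lacks %s",
            paste(setdiff(dirs, names(external_degs)), collapse = ", "))
  }
  lapply(setNames(nm = dirs), function(d) {
    g <- sort(intersect(concordant_sets[[d]], external_degs[[d]]))
    list(genes = g, count = length(g))
  })
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    unique(f[-c(1, 2)])
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  out
}
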