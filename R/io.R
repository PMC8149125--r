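# TSV interfaces. All tables are plain tab-separated files with a header
# row; column mapping is declared at the call site rather than guessed.

#' Read a tab-separated summary table with a declared column mapping
#'
#' @param path TSV file path.
#' @param col_map named character vector mapping internal column names
#'   (e.g. `gene_id`, `log2fc`, `p_value`) to column names in the file.
#'   Unmapped columns are kept as-is.
#' @return data.frame with renamed columns.
#' @export
read_tsv_mapped <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    miss <- setdiff(unname(col_map), names(df))
    if (length(miss)) stop_xc("file %s lacks mapped column(s): %s", path,
                              paste(miss, collapse = ", "))
    names(df)[match(col_map, names(df))] <- names(col_map)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise homology map
#'
#' Expected columns: `species_a`, `gene_a`, `species_b`, `gene_b`, and
#' optionally `score`.
#'
#' @param path TSV file path.
#' @return data.frame suitable for [build_merged_graph()].
#' @export
read_homology_map <- function(path) {
  df <- read_tsv_mapped(path)
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_xc("homology map %s lacks column(s): %s", path,
                            paste(miss, collapse = ", "))
  df
}

#' Write DEG calls as TSV
#'
#' Columns: `gene_id`, `species`, `direction`, `evidence` (semicolon-joined),
#' `conflict_flag`.
#'
#' @param calls a `deg_calls` data.frame.
#' @param path output file.
#' @export
write_deg_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls)[, c("gene_id", "species", "direction",
                                     "evidence", "conflict_flag")], path)
}

#' Write concordance components as TSV
#'
#' @param fit a `concordance` object.
#' @param path output file.
#' @export
write_concordance <- function(fit, path) {
  stopifnot(inherits(fit, "concordance"))
  write_tsv(fit$components, path)
}

#' Write a community partition as TSV (node, community)
#'
#' @param partition a `community_partition`.
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  a <- partition$assignment
  write_tsv(data.frame(node = names(a), community = unname(a),
                       stringsAsFactors = FALSE), path)
}

#' Write a simulated study to a directory of plain-text inputs
#'
#' Emits every pipeline input as TSV (homology maps, per-species DE summary
#' tables, interaction edges, background list, climbing records) plus a
#' `truth/` subdirectory holding the generator's ground-truth side channels.
#' Pipeline stages read only the inputs; the truth files exist for
#' benchmarking.
#'
#' @param sim output of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  for (i in seq_along(sim$universe$maps)) {
    m <- sim$universe$maps[[i]]
    write_tsv(m, file.path(outdir, sprintf("homology_%s_%s.tsv",
                                           m$species_a[1], m$species_b[1])))
  }
  write_tsv(sim$deg$human_probes, file.path(outdir, "human_probes.tsv"))
  write_tsv(sim$deg$mouse, file.path(outdir, "mouse_continuousQ.tsv"))
  write_tsv(sim$deg$fly$glia, file.path(outdir, "fly_glia.tsv"))
  write_tsv(sim$deg$fly$neuron, file.path(outdir, "fly_neuron.tsv"))
  write_tsv(sim$ppi$edges, file.path(outdir, "ppi_edges.tsv"))
  writeLines(sim$ppi$background, file.path(outdir, "background_proteome.txt"))
  write_tsv(sim$behavior$records, file.path(outdir, "climbing_records.tsv"))
  write_tsv(sim$universe$truth, file.path(outdir, "truth", "homology_components.tsv"))
  write_tsv(sim$deg$truth$members, file.path(outdir, "truth", "planted_degs.tsv"))
  write_tsv(sim$ppi$truth, file.path(outdir, "truth", "ppi_blocks.tsv"))
  write_tsv(sim$behavior$truth, file.path(outdir, "truth", "behavior_effects.tsv"))
  invisible(outdir)
}
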