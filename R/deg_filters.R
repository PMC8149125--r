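#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Step-up false discovery rate control. The adjusted value for the i-th
#' smallest p is `min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted p-values (same length and order).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) < 1L) {
    stop_xc("p_values must be a non-empty numeric vector")
  }
  check_prob(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}

new_deg_calls <- function(gene_id, species, direction, evidence, conflict_flag) {
  df <- data.frame(gene_id = as.character(gene_id),
                   species = as.character(species),
                   direction = as.character(direction),
                   evidence = as.character(evidence),
                   conflict_flag = as.logical(conflict_flag),
                   stringsAsFactors = FALSE)
  class(df) <- c("deg_calls", "data.frame")
  df
}

#' Call human DEGs from probe-level microarray summary statistics
#'
#' Applies the probe-existence rule used for patient caudate microarray data:
#' a gene is called dysregulated in a direction if at least one of its mapped
#' probes has absolute fold-change strictly greater than `fc_threshold` and
#' FDR strictly below `fdr_threshold`, with matching sign. FDR is computed by
#' [bh_adjust()] over all probes jointly when not supplied. Probes with a
#' missing (`NA`) `gene_id` are ignored.
#'
#' When significant probes of one gene disagree in sign, the gene is emitted
#' in both directions with `conflict_flag = TRUE`; downstream consumers may
#' drop flagged genes. This keeps the existence rule literal while making the
#' ambiguity visible.
#'
#' @param probe_stats data.frame with columns `probe_id`, `gene_id`,
#'   `fold_change`, `p_value` and optionally `fdr`.
#' @param fc_threshold linear fold-change threshold (strict `>`), default 1.2.
#' @param fdr_threshold FDR threshold (strict `<`), default 0.05.
#' @param fc_dialect `"linear"` (signed linear fold-change; sign encodes
#'   direction) or `"log2"`. Must be declared explicitly: there is no default,
#'   because silently mixing the two dialects shifts the threshold.
#' @param species species label attached to the calls, default `"human"`.
#' @return A `deg_calls` data.frame with columns `gene_id`, `species`,
#'   `direction`, `evidence` (semicolon-joined probe ids), `conflict_flag`.
#' @export
call_degs_human <- function(probe_stats, fc_threshold = 1.2,
                            fdr_threshold = 0.05, fc_dialect = NULL,
                            species = "human") {
  need <- c("probe_id", "gene_id", "fold_change", "p_value")
  miss <- setdiff(need, names(probe_stats))
  if (length(miss)) stop_xc("probe_stats lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(fc_dialect) || !fc_dialect %in% c("linear", "log2")) {
    stop_xc("fold-change dialect must be declared as \"linear\" or \"log2\"")
  }
  check_prob(probe_stats$p_value, "p_value")
  fc <- probe_stats$fold_change
  if (any(!is.finite(fc) | fc == 0)) stop_xc("fold_change must be finite and nonzero")

  fdr <- probe_stats$fdr %||% bh_adjust(probe_stats$p_value)
  mag <- if (fc_dialect == "log2") 2^abs(fc) else abs(fc)
  dir <- ifelse(fc > 0, "up", "down")
  if (fc_dialect == "linear" && any(abs(fc) < 1)) {
    # signed linear dialect: |FC| is the magnitude; values in (0,1) would be
    # an unsigned down-fold encoding, which this dialect does not use
    stop_xc("linear fold-change dialect requires signed values with |FC| >= 1")
  }

  pass <- mag > fc_threshold & fdr < fdr_threshold & !is.na(probe_stats$gene_id)
  if (!any(pass)) return(new_deg_calls(character(), character(), character(), character(), logical()))

  hits <- data.frame(gene_id = as.character(probe_stats$gene_id[pass]),
                     direction = dir[pass],
                     probe = as.character(probe_stats$probe_id[pass]),
                     stringsAsFactors = FALSE)
  ev <- aggregate(probe ~ gene_id + direction, data = hits,
                  FUN = function(p) paste(sort(unique(p)), collapse = ";"))
  both <- intersect(ev$gene_id[ev$direction == "up"], ev$gene_id[ev$direction == "down"])
  out <- new_deg_calls(ev$gene_id, species, ev$direction, ev$probe,
                       ev$gene_id %in% both)
  out[order(out$direction, out$gene_id), , drop = FALSE]
}

#' Call DEGs by the any-significant-contrast union rule
#'
#' A gene is called dysregulated in the direction of its log2 fold-change if
#' its FDR is strictly below `fdr_threshold` in at least one contrast
#' (model x driver x timepoint, or a single continuous-trait contrast).
#' Fold-change magnitude is ignored; only the direction matters. If the
#' significant contrasts of a gene disagree in sign, the gene is excluded
#' from both direction sets and reported in the `conflicts` attribute —
#' direction-specific concordance needs one direction per gene per species.
#'
#' @param stats data.frame with columns `gene_id`, `species`,
#'   `contrast_label`, `log2fc`, and `fdr` or `p_value` (FDR is computed per
#'   contrast by [bh_adjust()] when only raw p is present).
#' @param fdr_threshold FDR threshold (strict `<`), default 0.05.
#' @return A `deg_calls` data.frame (one row per gene and direction;
#'   `evidence` lists the passing contrast labels). Sign-conflicted genes are
#'   in `attr(, "conflicts")`, retrievable with [deg_conflicts()].
#' @export
call_degs_any_contrast <- function(stats, fdr_threshold = 0.05) {
  need <- c("gene_id", "species", "contrast_label", "log2fc")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop_xc("stats lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(stats$fdr)) {
    if (is.null(stats$p_value)) stop_xc("stats needs an fdr column or a p_value column")
    stats$fdr <- stats::ave(stats$p_value, stats$contrast_label, FUN = bh_adjust)
  }
  check_prob(stats$fdr, "fdr")

  sig <- stats[stats$fdr < fdr_threshold & stats$log2fc != 0, , drop = FALSE]
  empty <- new_deg_calls(character(), character(), character(), character(), logical())
  if (!nrow(sig)) {
    attr(empty, "conflicts") <- empty
    return(empty)
  }
  sig$direction <- ifelse(sig$log2fc > 0, "up", "down")
  key <- paste(sig$species, sig$gene_id, sep = "\r")
  ndir <- tapply(sig$direction, key, function(d) length(unique(d)))
  conflicted <- names(ndir)[ndir > 1L]
  is_conf <- key %in% conflicted

  collapse <- function(d) {
    if (!nrow(d)) return(empty)
    ev <- aggregate(contrast_label ~ gene_id + species + direction, data = d,
                    FUN = function(x) paste(sort(unique(x)), collapse = ";"))
    out <- new_deg_calls(ev$gene_id, ev$species, ev$direction,
                         ev$contrast_label, FALSE)
    out[order(out$species, out$direction, out$gene_id), , drop = FALSE]
  }
  calls <- collapse(sig[!is_conf, , drop = FALSE])
  conf <- collapse(sig[is_conf, , drop = FALSE])
  if (nrow(conf)) conf$conflict_flag <- TRUE
  attr(calls, "conflicts") <- conf
  calls
}

#' Sign-conflicted genes excluded by [call_degs_any_contrast()]
#'
#' @param calls a `deg_calls` object.
#' @return A `deg_calls` data.frame of the excluded, conflicted calls.
#' @export
deg_conflicts <- function(calls) {
  attr(calls, "conflicts") %||%
    new_deg_calls(character(), character(), character(), character(), logical())
}

#' Extract per-direction gene sets from DEG calls
#'
#' @param calls a `deg_calls` data.frame.
#' @param direction `"up"` or `"down"`.
#' @param drop_conflicts drop genes with `conflict_flag = TRUE` (default TRUE).
#' @return character vector of gene ids.
#' @export
deg_gene_set <- function(calls, direction = c("up", "down"),
                         drop_conflicts = TRUE) {
  direction <- match.arg(direction)
  keep <- calls$direction == direction
  if (drop_conflicts) keep <- keep & !calls$conflict_flag
  unique(calls$gene_id[keep])
}
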