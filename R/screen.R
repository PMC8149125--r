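#' Rank candidates within clusters by cumulative centrality rank-score
#'
#' Within each community, nodes are ranked descending by degree (rank 1 =
#' largest) and descending by betweenness, with average ranks for ties; the
#' rank-score is the sum of the two ranks, so low scores mark nodes that are
#' central by both measures. Candidates are ordered by ascending rank-score,
#' ties broken by higher degree, then lexicographic node id.
#'
#' @param partition a `community_partition`; unassigned (`NA`) nodes are
#'   skipped.
#' @param centrality a data.frame from [node_centrality()]; every assigned
#'   node must be present.
#' @return data.frame with columns `node`, `cluster`, `degree`,
#'   `betweenness`, `degree_rank`, `betweenness_rank`, `rank_score`,
#'   `overall_order` (1 = strongest candidate overall).
#' @export
centrality_rank_score <- function(partition, centrality) {
  stopifnot(inherits(partition, "community_partition"))
  a <- partition$assignment
  nodes <- names(a)[!is.na(a)]
  miss <- setdiff(nodes, centrality$node)
  if (length(miss)) {
    stop_xc("nodes missing from the centrality table: %s",
            paste(head(miss, 10L), collapse = ", "))
  }
  idx <- match(nodes, centrality$node)
  df <- data.frame(node = nodes, cluster = a[nodes],
                   degree = centrality$degree[idx],
                   betweenness = centrality$betweenness[idx],
                   stringsAsFactors = FALSE, row.names = NULL)
  df$degree_rank <- stats::ave(-df$degree, df$cluster,
                               FUN = function(x) rank(x, ties.method = "average"))
  df$betweenness_rank <- stats::ave(-df$betweenness, df$cluster,
                                    FUN = function(x) rank(x, ties.method = "average"))
  df$rank_score <- df$degree_rank + df$betweenness_rank
  ord <- order(df$rank_score, -df$degree, df$node)
  df <- df[ord, , drop = FALSE]
  df$overall_order <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

check_records <- function(records, arg = "records") {
  need <- c("genotype", "age_day", "replicate_id", "speed")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_xc("%s lacks column(s): %s", arg, paste(miss, collapse = ", "))
  if (any(records$speed < 0)) stop_xc("%s: speed must be >= 0", arg)
  if (any(records$age_day <= 0)) stop_xc("%s: age_day must be positive", arg)
  invisible(records)
}

#' Per-genotype, per-day trajectory summary
#'
#' @param records climbing-record data.frame with columns `genotype`,
#'   `age_day`, `replicate_id`, `speed`.
#' @return data.frame with `genotype`, `age_day`, `mean`, `sem`
#'   (`sd / sqrt(n)`, reported as 0 when `n = 1`), `n`, and `single_replicate`
#'   flagging the n = 1 convention.
#' @export
summarize_trajectory <- function(records) {
  check_records(records)
  agg <- aggregate(speed ~ genotype + age_day, data = records,
                   FUN = function(x) c(mean = mean(x),
                                       sem = if (length(x) > 1)
                                         stats::sd(x) / sqrt(length(x)) else 0,
                                       n = length(x)))
  out <- data.frame(genotype = agg$genotype, age_day = agg$age_day,
                    mean = agg$speed[, "mean"], sem = agg$speed[, "sem"],
                    n = as.integer(agg$speed[, "n"]),
                    stringsAsFactors = FALSE)
  out$single_replicate <- out$n == 1L
  out[order(out$genotype, out$age_day), , drop = FALSE]
}

shared_day_window <- function(exp_days, ctrl_days, day_window = NULL,
                              trial_length = 9) {
  shared <- sort(intersect(exp_days, ctrl_days))
  if (!length(shared)) stop_xc("no shared days between experimental and control")
  if (is.null(day_window)) {
    day_window <- c(shared[1], shared[1] + trial_length - 1)
  }
  shared[shared >= day_window[1] & shared <= day_window[2]]
}

#' Percent improvement of an experimental trajectory over the positive control
#'
#' The day-averaged relative difference of trajectory means:
#' `100 * mean_d[(mean_exp(d) - mean_ctrl(d)) / mean_ctrl(d)]` over the
#' shared days inside the trial window. Negative values indicate worsening.
#' Days on which the control day-mean is exactly 0 are excluded with a
#' warning (the relative difference is undefined there). The alternative
#' `"auc"` method integrates both mean trajectories by the trapezoid rule
#' and reports the area difference as a percentage of the control area.
#'
#' @param experimental,positive_control climbing-record data.frames (one
#'   genotype each, or pre-filtered).
#' @param day_window `c(first, last)` day range; defaults to the shared days
#'   clipped to `trial_length` days from trial start.
#' @param trial_length default trial window in days (9).
#' @param method `"mean_relative"` (default) or `"auc"`.
#' @return numeric scalar, the percent improvement.
#' @export
percent_improvement <- function(experimental, positive_control,
                                day_window = NULL, trial_length = 9,
                                method = c("mean_relative", "auc")) {
  method <- match.arg(method)
  check_records(experimental, "experimental")
  check_records(positive_control, "positive_control")
  se <- summarize_trajectory(experimental)
  sc <- summarize_trajectory(positive_control)
  days <- shared_day_window(se$age_day, sc$age_day, day_window, trial_length)
  me <- se$mean[match(days, se$age_day)]
  mc <- sc$mean[match(days, sc$age_day)]
  if (method == "mean_relative") {
    zero <- mc == 0
    if (any(zero)) {
      warning(sprintf("excluding %d day(s) with a control mean of 0", sum(zero)))
      me <- me[!zero]; mc <- mc[!zero]
    }
    if (!length(mc)) stop_xc("no usable days: every control day-mean is 0")
    100 * mean((me - mc) / mc)
  } else {
    trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
    if (length(days) < 2) stop_xc("auc method needs at least two shared days")
    ac <- trapz(days, mc)
    if (ac == 0) stop_xc("control area under the curve is 0")
    100 * (trapz(days, me) - ac) / ac
  }
}

#' Permutation test for a trajectory difference
#'
#' A label-permutation test of the behavioral effect size: the statistic is
#' `|percent_improvement|` on day-wise replicate means, and the null is
#' generated by permuting replicate-to-genotype labels within each shared
#' day. The p-value is `(r + 1) / (n_perm + 1)`. This is deliberately a
#' design-free substitute for curve-based mixed-effects inference: it tests
#' exchangeability of replicates between the two genotypes without modelling
#' the trajectory shape.
#'
#' @param experimental,positive_control climbing-record data.frames.
#' @param n_perm number of permutations, default 10000.
#' @param rng_seed integer seed.
#' @param day_window,trial_length as in [percent_improvement()].
#' @return list with `p_value`, `observed` (the signed percent improvement),
#'   `statistic` (its absolute value), `n_perm`, `seed`.
#' @export
trajectory_permutation_test <- function(experimental, positive_control,
                                        n_perm = 10000, rng_seed = NULL,
                                        day_window = NULL, trial_length = 9) {
  check_records(experimental, "experimental")
  check_records(positive_control, "positive_control")
  ne <- min(table(experimental$age_day))
  nc <- min(table(positive_control$age_day))
  if (ne < 3 || nc < 3) {
    stop_xc("permutation test needs >= 3 replicates per genotype per day")
  }
  se <- summarize_trajectory(experimental)
  sc <- summarize_trajectory(positive_control)
  days <- shared_day_window(se$age_day, sc$age_day, day_window, trial_length)
  obs <- percent_improvement(experimental, positive_control,
                             day_window = range(days))

  pools <- lapply(days, function(d) {
    list(e = experimental$speed[experimental$age_day == d],
         c = positive_control$speed[positive_control$age_day == d])
  })
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    rel <- vapply(pools, function(p) {
      pool <- c(p$e, p$c)
      pick <- sample.int(length(pool), length(p$e))
      m_e <- mean(pool[pick])
      m_c <- mean(pool[-pick])
      if (m_c == 0) NA_real_ else (m_e - m_c) / m_c
    }, numeric(1))
    rel <- rel[!is.na(rel)]
    if (!length(rel)) 0 else abs(100 * mean(rel))
  }, numeric(1))
  r <- sum(perm_stats >= abs(obs))
  list(p_value = (r + 1) / (n_perm + 1), observed = obs,
       statistic = abs(obs), n_perm = n_perm, seed = rng_seed)
}

#' Full screen score for one genotype: estimate, bootstrap CI, permutation p
#'
#' Combines [percent_improvement()] (point estimate), a replicate bootstrap
#' (percentile confidence interval; replicates resampled within genotype and
#' day), and [trajectory_permutation_test()].
#'
#' @param experimental,positive_control climbing-record data.frames.
#' @param genotype label for the output row.
#' @param day_window,trial_length as in [percent_improvement()].
#' @param n_boot bootstrap resamples for the CI, default 1000.
#' @param n_perm permutations, default 10000.
#' @param rng_seed integer seed (drives both bootstrap and permutation).
#' @param conf confidence level, default 0.95.
#' @return one-row data.frame: `genotype`, `percent_improvement`, `ci_low`,
#'   `ci_high`, `p_value`, `n_perm`, `seed`.
#' @export
screen_score <- function(experimental, positive_control, genotype = "experimental",
                         day_window = NULL, trial_length = 9,
                         n_boot = 1000, n_perm = 10000, rng_seed = NULL,
                         conf = 0.95) {
  est <- percent_improvement(experimental, positive_control, day_window,
                             trial_length)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  resample <- function(rec) {
    idx <- unlist(lapply(split(seq_len(nrow(rec)), rec$age_day), function(i) {
      i[sample.int(length(i), length(i), replace = TRUE)]
    }), use.names = FALSE)
    rec[idx, , drop = FALSE]
  }
  boot <- vapply(seq_len(n_boot), function(i) {
    tryCatch(suppressWarnings(
      percent_improvement(resample(experimental), resample(positive_control),
                          day_window, trial_length)),
      error = function(e) NA_real_)
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  perm <- trajectory_permutation_test(experimental, positive_control,
                                      n_perm = n_perm, rng_seed = NULL,
                                      day_window = day_window,
                                      trial_length = trial_length)
  data.frame(genotype = genotype, percent_improvement = est,
             ci_low = min(qs[1], est), ci_high = max(qs[2], est),
             p_value = perm$p_value, n_perm = n_perm,
             seed = rng_seed %||% NA_integer_,
             stringsAsFactors = FALSE)
}
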