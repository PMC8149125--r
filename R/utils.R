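#' @keywords internal
"_PACKAGE"

#' @import igraph
#' @importFrom stats p.adjust pnorm phyper sd rnorm runif rbinom aggregate setNames
#' @importFrom utils read.delim write.table head
NULL

SPECIES_LEVELS <- c("human", "mouse", "fly")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_xc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_species <- function(species, arg = "species") {
  bad <- setdiff(unique(species), SPECIES_LEVELS)
  if (length(bad)) {
    stop_xc("unknown %s label(s): %s (expected one of %s)",
            arg, paste(bad, collapse = ", "), paste(SPECIES_LEVELS, collapse = ", "))
  }
  invisible(species)
}

check_prob <- function(x, name) {
  bad <- which(!is.finite(x) | x < 0 | x > 1)
  if (length(bad)) {
    stop_xc("%s outside [0,1] at index: %s", name,
            paste(head(bad, 10L), collapse = ", "))
  }
  invisible(x)
}

#' Summarize a resampled null distribution against an observed statistic
#'
#' Given a vector of statistic values obtained under resampling, computes the
#' null mean and sample SD, the z-score of the observed value, a tail
#' probability from a normal approximation to the null, and the empirical
#' tail fraction `(r + 1) / (n + 1)`.
#'
#' The normal-approximation p-value is reported because an empirical tail can
#' never fall below `1 / (n + 1)`; extreme separations between observed and
#' null (z-scores of tens of SDs) are only expressible through the
#' approximation. Both values are always reported together.
#'
#' @param samples numeric vector of resampled statistic values.
#' @param observed observed value of the same statistic.
#' @param statistic_name label carried into reports.
#' @param tail one of `"upper"`, `"lower"`, `"two-sided"`.
#' @param seed the RNG seed used to generate `samples` (metadata only).
#' @return An object of class `null_distribution`: a list with elements
#'   `statistic_name`, `samples`, `n_samples`, `mean`, `sd`, `observed`,
#'   `z_score`, `p_normal`, `p_empirical`, `tail`, `seed`.
#' @export
null_distribution <- function(samples, observed, statistic_name = "statistic",
                              tail = c("upper", "lower", "two-sided"),
                              seed = NULL) {
  tail <- match.arg(tail)
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_xc("samples must be a non-empty numeric vector")
  }
  m <- mean(samples)
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0) {
    stop_xc(paste0("degenerate null: resampled statistic has zero variance; ",
                   "z and p are undefined (enlarge the background or sample size)"))
  }
  z <- (observed - m) / s
  p_normal <- switch(tail,
    upper = stats::pnorm(z, lower.tail = FALSE),
    lower = stats::pnorm(z),
    `two-sided` = 2 * stats::pnorm(-abs(z)))
  n <- length(samples)
  r <- switch(tail,
    upper = sum(samples >= observed),
    lower = sum(samples <= observed),
    `two-sided` = sum(abs(samples - m) >= abs(observed - m)))
  p_emp <- (r + 1) / (n + 1)
  structure(list(statistic_name = statistic_name, samples = samples,
                 n_samples = n, mean = m, sd = s, observed = observed,
                 z_score = z, p_normal = p_normal, p_empirical = p_emp,
                 tail = tail, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Resampling null for '%s' (%d samples, %s tail)\n",
              x$statistic_name, x$n_samples, x$tail))
  cat(sprintf("  null mean %.4g, sd %.4g\n", x$mean, x$sd))
  cat(sprintf("  observed %.4g  ->  z = %.3f, p(normal) = %.4g, p(empirical) = %.4g\n",
              x$observed, x$z_score, x$p_normal, x$p_empirical))
  invisible(x)
}

#' Serialize a null-distribution report to JSON
#'
#' @param x a `null_distribution` object.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
null_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "null_distribution"))
  rep <- list(statistic = x$statistic_name, observed = x$observed,
              n_samples = x$n_samples, mean = x$mean, sd = x$sd,
              z = x$z_score, p_normal = x$p_normal,
              p_empirical = x$p_empirical, seed = x$seed)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# Derive a per-iteration RNG seed stream from one user seed, keeping values
# inside the 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  (as.integer(seed) + seq_len(n) * 7919L) %% .Machine$integer.max
}
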