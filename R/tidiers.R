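#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Kolmogorov-Smirnov comparison
#'
#' @param x A `ks_result`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, critical value, p-value,
#'   sample sizes and the conjunction-rule call.
#' @export
tidy.ks_result <- function(x, ...) {
  tibble(d_obs = x$d_obs, d_crit = x$d_crit, p.value = x$p,
         n1 = x$n1, n2 = x$n2, alpha = x$alpha, significant = x$significant)
}

#' @rdname tidy.ks_result
#' @export
glance.ks_result <- function(x, ...) tidy(x)

#' Tidy a gene-identity permutation test
#'
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return One-row tibble with observed value, null summary, z, p and
#'   alternative.
#' @export
tidy.perm_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = sd(x$null_values), z = x$z,
         p.value = x$p, alternative = x$alternative, n_perm = x$n_perm)
}

#' @rdname tidy.perm_result
#' @export
glance.perm_result <- function(x, ...) tidy(x)

#' Tidy a window co-localization null comparison
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return One-row tibble with observed occupancy, co-localization
#'   percentage, null mean and both p-values.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(n_query = x$n_query, n_occupied = x$n_occupied,
         n_colocalized = x$n_colocalized,
         pct_colocalized = x$pct_colocalized,
         null_mean = x$null_mean, empirical_p = x$empirical_p,
         ranksum_p = x$ranksum_p, draws = x$draws)
}

#' @rdname tidy.coloc_result
#' @export
glance.coloc_result <- function(x, ...) tidy(x)

#' Tidy a zero-expression Fisher test
#'
#' @param x A `zero_test`.
#' @param ... Unused.
#' @return One-row tibble with per-genotype zero counts, odds ratio and p.
#' @export
tidy.zero_test <- function(x, ...) {
  tibble(zero_a = x$counts[1, "zero"], nonzero_a = x$counts[1, "nonzero"],
         zero_b = x$counts[2, "zero"], nonzero_b = x$counts[2, "nonzero"],
         odds_ratio = x$odds_ratio, p.value = x$p, p_floored = x$p_floored)
}

#' Tidy a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return One-row tibble with genotype, covered bases, genome size and
#'   fraction.
#' @export
tidy.coverage_report <- function(x, ...) {
  tibble(genotype = x$genotype, n_alignments_used = x$n_alignments_used,
         bases_covered = x$bases_covered, genome_size = x$genome_size,
         fraction = x$fraction, min_reads = x$min_reads)
}
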