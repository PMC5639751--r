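#' Filter an expression table to expressed genes
#'
#' Keeps rows whose test status is `OK` in at least one analysis column.
#' When no status columns are present, the fallback rule keeps rows with
#' FPKM >= 1 in at least one genotype (genes below 1 FPKM everywhere are
#' treated as not expressed).
#'
#' @param table Expression tibble. Status columns are those named in
#'   `status_cols` (default: every column starting with `status`); FPKM
#'   columns default to every column starting with `fpkm`.
#' @param status_cols,fpkm_cols Optional explicit column names.
#' @return The filtered tibble.
#' @export
filter_expressed <- function(table, status_cols = NULL, fpkm_cols = NULL) {
  status_cols <- status_cols %||% grep("^status", names(table), value = TRUE)
  fpkm_cols <- fpkm_cols %||% grep("^fpkm", names(table), value = TRUE)
  if (nrow(table) == 0) return(table)
  if (length(status_cols) > 0) {
    keep <- Reduce(`|`, lapply(status_cols, function(cl) table[[cl]] == "OK"))
  } else if (length(fpkm_cols) > 0) {
    keep <- Reduce(`|`, lapply(fpkm_cols, function(cl) table[[cl]] >= 1))
  } else {
    abort("filter_expressed: table has neither status nor fpkm columns")
  }
  table[keep %in% TRUE, ]
}

#' Fisher exact test on zero-expression frequencies
#'
#' Builds the 2x2 table of zero vs non-zero FPKM counts by genotype and
#' applies the two-sided Fisher exact test (summing hypergeometric
#' probabilities no larger than the observed table's). A p-value below
#' 1e-15 is floored there and flagged, so an exact zero is never reported.
#'
#' @param table Filtered expression tibble.
#' @param genotypes Character vector of two genotype labels; FPKM columns
#'   `fpkm_<genotype>` must exist.
#' @return List of class `zero_test` with `counts` (2x2 matrix), `odds_ratio`,
#'   `p`, `p_floored`.
#' @export
zero_fraction_test <- function(table, genotypes = c("wt", "mut")) {
  cols <- paste0("fpkm_", genotypes)
  stopifnot_cols(table, cols, "table")
  counts <- vapply(cols, function(cl) {
    v <- table[[cl]]
    if (length(v) == 0) abort(sprintf("zero_fraction_test: no rows for %s", cl))
    c(zero = sum(v == 0), nonzero = sum(v > 0))
  }, double(2))
  m <- t(counts)  # rows: genotypes; cols: zero, nonzero
  dimnames(m) <- list(genotypes, c("zero", "nonzero"))
  if (all(m[, "zero"] == 0)) {
    return(structure(list(counts = m, odds_ratio = NA_real_, p = 1,
                          p_floored = FALSE, odds_ratio_undefined = TRUE),
                     class = "zero_test"))
  }
  ft <- fisher.test(m)
  p <- ft$p.value
  floored <- p < 1e-15
  structure(list(counts = m, odds_ratio = unname(ft$estimate),
                 p = max(p, 1e-15), p_floored = floored,
                 odds_ratio_undefined = FALSE),
            class = "zero_test")
}

# two-sided asymptotic Kolmogorov distribution tail:
# P(sqrt(n) D > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_p <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- if (lambda < 1) {
    # dual (Jacobi theta) series: numerically stable for small lambda
    1 - sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
  } else {
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  min(1, max(p, 1e-300))
}

#' Two-sample Kolmogorov-Smirnov comparison with a D-crit decision rule
#'
#' Computes the observed statistic `D_obs = sup |ECDF_x - ECDF_y|`
#' (invariant to the log2 display transform), the critical distance
#' `D_crit = c(alpha) * sqrt((n1 + n2) / (n1 * n2))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)` (1.62762 at alpha = 0.01), and
#' the asymptotic Kolmogorov p-value. The two distributions are declared
#' different only when both `D_obs > D_crit` and `p < alpha`.
#'
#' @param x,y Numeric samples of strictly positive FPKM (zeros must be
#'   removed upstream; they are handled by [zero_fraction_test()]).
#' @param alpha Significance level of the conjunction rule (default 0.01).
#' @return A list of class `ks_result` with `d_obs`, `d_crit`, `p`, `n1`,
#'   `n2`, `alpha`, `significant`.
#' @export
ks_compare <- function(x, y, alpha = 0.01) {
  if (length(x) == 0 || length(y) == 0) abort("ks_compare: empty sample")
  if (any(x <= 0) || any(y <= 0)) {
    abort("ks_compare: samples must be strictly positive (remove zeros upstream)")
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 < 8 || n2 < 8) {
    warn("ks_compare: a sample has fewer than 8 observations; the asymptotic p-value is unreliable")
  }
  w <- c(x, y)
  o <- order(w)
  steps <- ifelse(o <= n1, 1 / n1, -1 / n2)
  z <- cumsum(steps)
  ws <- w[o]
  at_jump <- c(diff(ws) != 0, TRUE)  # evaluate only where the pooled value changes
  d_obs <- max(abs(z[at_jump]))
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  d_crit <- c_alpha * sqrt((n1 + n2) / (n1 * n2))
  p <- kolmogorov_p(sqrt(n1 * n2 / (n1 + n2)) * d_obs)
  structure(list(d_obs = d_obs, d_crit = d_crit, p = p,
                 n1 = n1, n2 = n2, alpha = alpha,
                 significant = d_obs > d_crit && p < alpha),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D-obs = %.4f, D-crit = %.4f, p = %.3g (n1 = %d, n2 = %d): %s\n",
              x$d_obs, x$d_crit, x$p, x$n1, x$n2,
              if (x$significant) "distributions differ" else "no difference called"))
  invisible(x)
}

#' Bin positive FPKM values on the log2 scale
#'
#' Positive values fall into unit-width bins centred on integer log2
#' values (bin k covers log2 FPKM in `[k - 0.5, k + 0.5)`: bin 0 is
#' FPKM = 1, bin 2 is FPKM = 4). Zeros are diverted to a separately held
#' zero fraction and never binned.
#'
#' @param fpkm Non-negative numeric sample.
#' @return List of class `binned_distribution`: `bins` tibble
#'   (`bin`, `n`, `frequency`, `cumulative` over positive values),
#'   `zero_fraction`, `n_positive`.
#' @export
binned_distribution <- function(fpkm) {
  if (any(fpkm < 0)) abort("binned_distribution: negative FPKM")
  n <- length(fpkm)
  pos <- fpkm[fpkm > 0]
  zero_fraction <- if (n == 0) 0 else (n - length(pos)) / n
  if (length(pos) == 0) {
    bins <- tibble(bin = integer(), n = integer(),
                   frequency = double(), cumulative = double())
  } else {
    b <- floor(log2(pos) + 0.5)
    grid <- seq(min(b), max(b))
    cnt <- tabulate(b - min(b) + 1L, nbins = length(grid))
    bins <- tibble(bin = as.integer(grid), n = cnt,
                   frequency = cnt / length(pos),
                   cumulative = cumsum(cnt) / length(pos))
  }
  structure(list(bins = bins, zero_fraction = zero_fraction,
                 n_positive = length(pos)),
            class = "binned_distribution")
}

#' Maximum distance between two binned cumulative curves
#'
#' Evaluates both cumulative frequency curves on the union bin grid
#' (carrying each curve forward across missing bins) and returns
#' `100 * max |cum_a - cum_b|`, the percentage separation of the two
#' cumulative expression curves.
#'
#' @param a,b `binned_distribution` objects.
#' @return Percentage (numeric scalar).
#' @export
max_cumulative_distance <- function(a, b) {
  stopifnot(inherits(a, "binned_distribution"), inherits(b, "binned_distribution"))
  if (nrow(a$bins) == 0 || nrow(b$bins) == 0) {
    return(if (nrow(a$bins) == nrow(b$bins)) 0 else 100)
  }
  grid <- seq(min(a$bins$bin, b$bins$bin), max(a$bins$bin, b$bins$bin))
  step_cum <- function(bd) {
    cum <- numeric(length(grid))
    cur <- 0
    for (i in seq_along(grid)) {
      j <- match(grid[i], bd$bins$bin)
      if (!is.na(j)) cur <- bd$bins$cumulative[j]
      cum[i] <- cur
    }
    cum
  }
  100 * max(abs(step_cum(a) - step_cum(b)))
}

#' Two-sided Mann-Whitney rank test
#'
#' Exact enumeration when `n1 * n2 <= 400` and the pooled sample has no
#' ties; otherwise the normal approximation with average ranks for ties,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `u` (the U statistic for `x`) and `p`.
#' @export
rank_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("rank_compare: empty sample")
  exact <- length(x) * length(y) <= 400 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}
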