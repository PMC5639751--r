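#' Tile a genome into non-overlapping windows
#'
#' @param genome Tibble (`chrom`, `length`).
#' @param width Window width in bp (default 100 kb). The last window of
#'   each chromosome is truncated at the chromosome end.
#' @return Tibble `window_id`, `chrom`, `start`, `end`.
#' @export
make_windows <- function(genome, width = 100000L) {
  stopifnot_cols(genome, c("chrom", "length"), "genome")
  if (width <= 0) abort("make_windows: width must be positive")
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    starts <- seq(0L, L - 1L, by = width)
    tibble(chrom = genome$chrom[i], start = as.integer(starts),
           end = as.integer(pmin(starts + width, L)))
  }) |>
    mutate(window_id = row_number()) |>
    select("window_id", "chrom", "start", "end")
}

# window id containing each gene's 5'-most oriented coordinate (its TSS),
# so a window-spanning gene is counted exactly once
assign_gene_windows <- function(genes, windows) {
  check_intervals(genes, "genes")
  pos <- if ("strand" %in% names(genes)) {
    tss_of(genes$start, genes$end, genes$strand)
  } else {
    genes$start
  }
  pts <- tibble(chrom = genes$chrom, start = pos, end = pos + 1L)
  hits <- interval_intersect(pts, windows)
  wid <- rep(NA_integer_, nrow(genes))
  wid[hits$idx_a] <- windows$window_id[hits$idx_b]
  wid
}

#' Per-window gene and DE-gene occupancy statistics
#'
#' Gene content of each window is normalised by the number of genes on the
#' window's chromosome; the number of differentially expressed genes in
#' each window is normalised by the window's gene content.
#'
#' @param windows Tibble from [make_windows()].
#' @param genes Gene tibble (each gene is assigned to the single window
#'   containing its 5' end).
#' @param de_genes Character vector of DE gene ids; must be a subset of
#'   `genes$gene_id`.
#' @return Tibble `window_id`, `chrom`, `start`, `end`, `n_genes`,
#'   `pct_of_chrom_genes`, `n_de`, `pct_de_of_window` (`NA` for windows
#'   with no genes).
#' @export
window_occupancy <- function(windows, genes, de_genes = character()) {
  if (!all(de_genes %in% genes$gene_id)) {
    abort("window_occupancy: de_genes must be a subset of genes$gene_id")
  }
  wid <- assign_gene_windows(genes, windows)
  per_win <- tibble(window_id = wid, de = genes$gene_id %in% de_genes) |>
    filter(!is.na(.data$window_id)) |>
    group_by(.data$window_id) |>
    summarise(n_genes = dplyr::n(), n_de = sum(.data$de), .groups = "drop")
  out <- windows |>
    left_join(per_win, by = "window_id") |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes),
           n_de = ifelse(is.na(.data$n_de), 0L, .data$n_de))
  chrom_tot <- out |>
    group_by(.data$chrom) |>
    summarise(chrom_genes = sum(.data$n_genes), .groups = "drop")
  out |>
    left_join(chrom_tot, by = "chrom") |>
    mutate(pct_of_chrom_genes = ifelse(.data$chrom_genes > 0,
                                       .data$n_genes / .data$chrom_genes, NA_real_),
           pct_de_of_window = ifelse(.data$n_genes > 0,
                                     .data$n_de / .data$n_genes, NA_real_)) |>
    select("window_id", "chrom", "start", "end", "n_genes",
           "pct_of_chrom_genes", "n_de", "pct_de_of_window")
}

#' Co-localization of a query gene set in genome windows
#'
#' Counts the distinct windows occupied by the query genes; the excess of
#' genes over occupied windows is the number of co-localized genes (genes
#' sharing a window with another query gene).
#'
#' @param query_genes Gene tibble (non-empty).
#' @param windows Tibble from [make_windows()].
#' @return One-row tibble `n_query`, `n_occupied`, `n_colocalized`,
#'   `pct_colocalized` (percent, 2 decimals half-up).
#' @export
colocalization <- function(query_genes, windows) {
  if (nrow(query_genes) == 0) abort("colocalization: empty query gene set")
  wid <- assign_gene_windows(query_genes, windows)
  n_query <- nrow(query_genes)
  n_occupied <- dplyr::n_distinct(wid[!is.na(wid)])
  tibble(n_query = n_query,
         n_occupied = n_occupied,
         n_colocalized = n_query - n_occupied,
         pct_colocalized = round_half_up(100 * (n_query - n_occupied) / n_query, 2))
}

#' Random-gene-set null for window co-localization
#'
#' Draws `draws` same-size gene sets without replacement from the
#' expressed-gene universe and counts the windows each occupies. The
#' one-sided empirical p treats fewer occupied windows (more clustering)
#' as extreme: `p = (1 + #draws with occupied <= observed) / (draws + 1)`.
#' A two-sided Wilcoxon rank-sum p compares the observed per-window query
#' counts against the pooled per-window null counts.
#'
#' @param query_genes Tibble of query genes (e.g. up-regulated set).
#' @param universe Tibble of all eligible genes; the query ids must be a
#'   subset and `nrow(query_genes) <= nrow(universe)`.
#' @param windows Tibble from [make_windows()].
#' @param draws Number of random gene sets (default 100).
#' @param seed Integer RNG seed.
#' @return List of class `coloc_result`: observed colocalization fields,
#'   `null_occupied` (per-draw counts), `null_mean`, `empirical_p`,
#'   `ranksum_p`, `draws`.
#' @export
random_geneset_null <- function(query_genes, universe, windows,
                                draws = 100L, seed = 1L) {
  k <- nrow(query_genes)
  if (k > nrow(universe)) abort("random_geneset_null: query larger than universe")
  obs <- colocalization(query_genes, windows)
  wid_universe <- assign_gene_windows(universe, windows)
  wid_query <- assign_gene_windows(query_genes, windows)
  null_occupied <- with_seed(seed, {
    vapply(seq_len(draws), function(d) {
      pick <- sample.int(nrow(universe), k)  # no duplicated entries per draw
      dplyr::n_distinct(wid_universe[pick][!is.na(wid_universe[pick])])
    }, double(1))
  })
  count_per_window <- function(wid) {
    tabulate(wid[!is.na(wid)], nbins = nrow(windows))
  }
  obs_counts <- count_per_window(wid_query)
  null_counts <- with_seed(seed, {
    unlist(lapply(seq_len(draws), function(d) {
      pick <- sample.int(nrow(universe), k)
      count_per_window(wid_universe[pick])
    }))
  })
  ranksum_p <- suppressWarnings(
    wilcox.test(obs_counts, null_counts, exact = FALSE)$p.value
  )
  structure(c(as.list(obs), list(
    null_occupied = null_occupied,
    null_mean = mean(null_occupied),
    empirical_p = (1 + sum(null_occupied <= obs$n_occupied)) / (draws + 1),
    ranksum_p = ranksum_p,
    draws = as.integer(draws)
  )), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d genes in %d windows (%.2f%% co-localized); null mean %.1f windows, empirical p = %.4g\n",
              x$n_query, x$n_occupied, x$pct_colocalized,
              x$null_mean, x$empirical_p))
  invisible(x)
}
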