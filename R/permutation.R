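#' Assign DE genes to fold-change quartile bins
#'
#' After filtering to `|log2FC| > lfc_cutoff` and `FDR < fdr_cutoff`,
#' up- and down-regulated genes are binned separately on fold-change
#' magnitude: bin 1 below the first quartile, bin 2 inside the
#' interquartile range (boundary values inclusive), bin 3 above the third
#' quartile. Down-regulated bins are reported as -1, -2, -3. Quartiles use
#' type-7 linear interpolation.
#'
#' @param de_table Tibble with `gene_id`, `log2fc`, `fdr`.
#' @param lfc_cutoff Strict absolute log2 fold-change cutoff (default 1).
#' @param fdr_cutoff Strict FDR cutoff (default 0.05).
#' @return Tibble `gene_id`, `log2fc`, `direction` (`up`/`down`), `bin`
#'   (signed integer).
#' @export
assign_expression_bins <- function(de_table, lfc_cutoff = 1, fdr_cutoff = 0.05) {
  stopifnot_cols(de_table, c("gene_id", "log2fc", "fdr"), "de_table")
  de <- filter(de_table, abs(.data$log2fc) > lfc_cutoff, .data$fdr < fdr_cutoff)
  bin_one <- function(d, sgn) {
    if (nrow(d) == 0) return(d[0, c("gene_id", "log2fc")])
    if (nrow(d) < 4) {
      abort(sprintf("assign_expression_bins: fewer than 4 %s-regulated genes; quartiles undefined",
                    if (sgn > 0) "up" else "down"))
    }
    m <- abs(d$log2fc)
    q <- quantile(m, c(0.25, 0.75), type = 7, names = FALSE)
    bin <- ifelse(m < q[1], 1L, ifelse(m > q[2], 3L, 2L))
    mutate(d, direction = if (sgn > 0) "up" else "down", bin = sgn * bin)
  }
  bind_rows(
    bin_one(filter(de, .data$log2fc > 0), 1L),
    bin_one(filter(de, .data$log2fc < 0), -1L)
  ) |>
    select("gene_id", "log2fc", "direction", "bin")
}

#' Gene-identity permutation test
#'
#' Compares `evaluator(regions)` against its distribution over `n_perm`
#' same-size gene sets sampled without replacement from the universe
#' (identity resampling, not coordinate shuffling). The alternative is
#' chosen by the deviation direction of the observed value from the null
#' mean, with a one-sided add-one-corrected p:
#' `p = (1 + #null at least as extreme) / (n_perm + 1)`.
#'
#' @param region_ids Character vector of query gene ids.
#' @param universe_ids Character vector of universe gene ids (the query
#'   must be a subset).
#' @param evaluator Function mapping a character vector of gene ids to a
#'   scalar (see [evaluator_mean_distance()] and
#'   [evaluator_mean_methylation()]).
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer RNG seed.
#' @return List of class `perm_result`: `observed`, `null_values`,
#'   `null_mean`, `z`, `p`, `alternative`, `n_perm`.
#' @export
permutation_test <- function(region_ids, universe_ids, evaluator,
                             n_perm = 200L, seed = 1L) {
  if (length(region_ids) > length(universe_ids)) {
    abort("permutation_test: more regions than universe members")
  }
  if (!all(region_ids %in% universe_ids)) {
    abort("permutation_test: regions must be a subset of the universe")
  }
  observed <- evaluator(region_ids)
  if (!is.finite(observed)) abort("permutation_test: evaluator undefined on the observed set")
  k <- length(region_ids)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      v <- evaluator(sample(universe_ids, k))
      if (!is.finite(v)) abort(sprintf("permutation_test: evaluator undefined on draw %d", i))
      v
    }, double(1))
  })
  null_mean <- mean(null_values)
  null_sd <- sd(null_values)
  alternative <- if (observed >= null_mean) "greater" else "less"
  extreme <- if (alternative == "greater") {
    sum(null_values >= observed)
  } else {
    sum(null_values <= observed)
  }
  structure(list(
    observed = observed,
    null_values = null_values,
    null_mean = null_mean,
    z = if (is.na(null_sd) || null_sd == 0) NA_real_ else (observed - null_mean) / null_sd,
    p = (1 + extreme) / (n_perm + 1),
    alternative = alternative,
    n_perm = as.integer(n_perm)
  ), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed = %.4g vs null mean %.4g (alternative: %s), p = %.4g [n_perm = %d]\n",
              x$observed, x$null_mean, x$alternative, x$p, x$n_perm))
  invisible(x)
}

#' Mean nearest-TE distance of a gene set
#'
#' Arithmetic mean of edge-to-edge nearest-TE gap distances. Genes on
#' chromosomes without a TE are excluded; their count is attached as the
#' `n_excluded` attribute.
#'
#' @param genes Gene tibble.
#' @param tes TE tibble.
#' @return Mean distance in bp.
#' @export
mean_te_distance <- function(genes, tes) {
  d <- nearest_te_distance(genes, tes)$nearest_te_distance
  if (all(is.na(d))) abort("mean_te_distance: no gene has a same-chromosome TE")
  structure(mean(d, na.rm = TRUE), n_excluded = sum(is.na(d)))
}

#' Evaluator factory: mean nearest-TE distance
#'
#' Precomputes per-gene nearest-TE distances once, then evaluates any gene
#' subset as the mean of its members' distances (NA-excluded). Suitable as
#' the `evaluator` of [permutation_test()]; identity resampling makes each
#' permutation a constant-time mean over the precomputed vector.
#'
#' @param genes Gene tibble (universe).
#' @param tes TE tibble.
#' @return A function of a character vector of gene ids.
#' @export
evaluator_mean_distance <- function(genes, tes) {
  nd <- nearest_te_distance(genes, tes)
  d <- setNames(nd$nearest_te_distance, nd$gene_id)
  function(ids) mean(d[ids], na.rm = TRUE)
}

# per-gene mean methylation over the strand-oriented flank(s)
flank_gene_means <- function(genes, track, flank, side) {
  check_intervals(genes, "genes", strand_required = TRUE)
  stopifnot_cols(track, c("chrom", "pos", "level"), "track")
  if (flank <= 0) abort("flank must be positive")
  tss <- tss_of(genes$start, genes$end, genes$strand)
  tts <- tts_of(genes$start, genes$end, genes$strand)
  plus <- genes$strand == "+"
  wins <- list()
  if (side %in% c("upstream", "both")) {
    wins$up <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = pmax(0L, ifelse(plus, tss - flank, tss + 1L)),
                      end = ifelse(plus, tss, tss + flank + 1L))
  }
  if (side %in% c("downstream", "both")) {
    wins$down <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = pmax(0L, ifelse(plus, tts + 1L, tts - flank)),
                        end = ifelse(plus, tts + flank + 1L, tts))
  }
  win <- bind_rows(wins)
  pts <- tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L)
  hits <- interval_intersect(win, pts)
  per_gene <- tibble(gene_id = win$gene_id[hits$idx_a],
                     level = track$level[hits$idx_b]) |>
    group_by(.data$gene_id) |>
    summarise(mean_level = mean(.data$level), .groups = "drop")
  out <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  out[per_gene$gene_id] <- per_gene$mean_level
  out
}

#' Mean flank methylation of a gene set
#'
#' Mean of per-gene flank means; each per-gene mean averages the track
#' positions falling in the strand-oriented flank window. Genes with no
#' covered position are excluded (count in attribute `n_excluded`).
#'
#' @param genes Gene tibble.
#' @param track Methylation tibble (`chrom`, `pos`, `level`), one context.
#' @param flank Flank width in bp (2000 for CG/CHG, 1000 for CHH by
#'   convention).
#' @param side `"upstream"`, `"downstream"` or `"both"`.
#' @return Mean methylation level in `[0, 1]`.
#' @export
mean_flank_methylation <- function(genes, track, flank = 2000L,
                                   side = c("both", "upstream", "downstream")) {
  side <- match.arg(side)
  m <- flank_gene_means(genes, track, flank, side)
  if (all(is.na(m))) abort("mean_flank_methylation: no gene flank covered by the track")
  structure(mean(m, na.rm = TRUE), n_excluded = sum(is.na(m)))
}

#' Evaluator factory: mean flank methylation
#'
#' Precomputes per-gene flank means once; evaluates a gene subset as the
#' mean over its members (NA-excluded). For [permutation_test()].
#'
#' @inheritParams mean_flank_methylation
#' @return A function of a character vector of gene ids.
#' @export
evaluator_mean_methylation <- function(genes, track, flank = 2000L,
                                       side = c("both", "upstream", "downstream")) {
  side <- match.arg(side)
  m <- flank_gene_means(genes, track, flank, side)
  function(ids) mean(m[ids], na.rm = TRUE)
}

#' Flanking-region methylation metaplot
#'
#' Divides the strand-oriented upstream and downstream flanks into
#' fixed-width windows (upstream windows indexed `-flank/window .. -1`
#' relative to the TSS, downstream `+1 .. +flank/window` relative to the
#' TTS) and averages the track level over all covered positions pooled
#' across genes (position-weighted).
#'
#' @param genes Gene tibble.
#' @param track Methylation tibble (`chrom`, `pos`, `level`), one context.
#' @param flank Flank width in bp; must be divisible by `window`.
#' @param window Window width in bp (default 100).
#' @return Tibble `window_index`, `side`, `n_positions`, `mean_level`
#'   (`NA` where no position is covered).
#' @export
flank_methylation_profile <- function(genes, track, flank = 2000L, window = 100L) {
  check_intervals(genes, "genes", strand_required = TRUE)
  if (flank %% window != 0) abort("flank must be divisible by window")
  tss <- tss_of(genes$start, genes$end, genes$strand)
  tts <- tts_of(genes$start, genes$end, genes$strand)
  plus <- genes$strand == "+"
  k <- as.integer(flank / window)

  collect <- function(anchor, upstream) {
    win <- if (upstream) {
      tibble(chrom = genes$chrom,
             start = pmax(0L, ifelse(plus, anchor - flank, anchor + 1L)),
             end = ifelse(plus, anchor, anchor + flank + 1L))
    } else {
      tibble(chrom = genes$chrom,
             start = pmax(0L, ifelse(plus, anchor + 1L, anchor - flank)),
             end = ifelse(plus, anchor + flank + 1L, anchor))
    }
    pts <- tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L)
    hits <- interval_intersect(win, pts)
    if (nrow(hits) == 0) {
      return(tibble(window_index = integer(), level = double()))
    }
    g <- hits$idx_a
    pos <- track$pos[hits$idx_b]
    off <- ifelse(plus[g], pos - anchor[g], anchor[g] - pos)  # oriented offset
    idx <- if (upstream) {
      as.integer(floor(off / window))        # -k .. -1
    } else {
      as.integer(ceiling(off / window))      # +1 .. +k
    }
    tibble(window_index = idx, level = track$level[hits$idx_b])
  }
  hits <- bind_rows(
    mutate(collect(tss, TRUE), side = "upstream"),
    mutate(collect(tts, FALSE), side = "downstream")
  )
  grid <- bind_rows(
    tibble(window_index = seq(-k, -1L), side = "upstream"),
    tibble(window_index = seq(1L, k), side = "downstream")
  )
  hits |>
    group_by(.data$window_index, .data$side) |>
    summarise(n_positions = dplyr::n(), mean_level = mean(.data$level),
              .groups = "drop") |>
    dplyr::right_join(grid, by = c("window_index", "side")) |>
    mutate(n_positions = ifelse(is.na(.data$n_positions), 0L, .data$n_positions)) |>
    arrange(.data$window_index)
}
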