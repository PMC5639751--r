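test_that("fold-change quartile bins follow the stated interpolation and boundary rules", {
  de <- tibble::tibble(gene_id = letters[1:8], log2fc = 1:8, fdr = 0.001)
  bins <- assign_expression_bins(de, lfc_cutoff = 0)   # values are pre-filtered
  expect_equal(bins$bin[bins$log2fc == 1], 1L)   # below Q1 = 2.75
  expect_equal(bins$bin[bins$log2fc == 4], 2L)   # inside IQR
  expect_equal(bins$bin[bins$log2fc == 8], 3L)   # above Q3 = 6.25
  # the |log2FC| > 1 filter is strict
  de2 <- tibble::tibble(gene_id = letters[1:6], log2fc = c(0.5, 2, 3, 4, 5, 6),
                        fdr = 0.001)
  expect_false("a" %in% assign_expression_bins(de2)$gene_id)
  # boundary values land in bin 2
  deq <- tibble::tibble(gene_id = letters[1:5], log2fc = c(2, 2, 3, 4, 4),
                        fdr = 0.001)
  bq <- assign_expression_bins(deq)
  expect_true(all(bq$bin[bq$log2fc %in% c(2, 4)] == 2L))
  # down-regulated bins are negative and computed on magnitude
  down <- tibble::tibble(gene_id = letters[1:8], log2fc = -(2:9), fdr = 0.001)
  bd <- assign_expression_bins(down)
  expect_equal(sort(unique(bd$bin)), c(-3L, -2L, -1L))
  expect_equal(bd$bin[bd$log2fc == -9], -3L)
  expect_error(assign_expression_bins(
    tibble::tibble(gene_id = c("a", "b"), log2fc = c(2, 3), fdr = 0.001)),
    "fewer than 4")
  same <- assign_expression_bins(
    tibble::tibble(gene_id = letters[1:5], log2fc = 3, fdr = 0.001))
  expect_true(all(same$bin == 2L))
})

test_that("permutation test degenerates correctly and respects the add-one floor", {
  ids <- sprintf("g%02d", 1:30)
  score <- setNames(runif(30), ids)
  ev <- function(x) mean(score[x])
  all_of_them <- permutation_test(ids, ids, ev, n_perm = 50L, seed = 1L)
  expect_equal(all_of_them$p, 1)
  expect_equal(all_of_them$observed, all_of_them$null_mean)
  const <- permutation_test(ids[1:5], ids, function(x) 1, n_perm = 50L, seed = 1L)
  expect_true(is.na(const$z))
  expect_equal(const$p, 1)
  expect_error(permutation_test(c(ids, "extra"), ids, ev), "subset|more regions")
  r <- permutation_test(ids[1:5], ids, ev, n_perm = 99L, seed = 2L)
  expect_gte(r$p, 1 / 100)
  expect_identical(r$null_values,
                   permutation_test(ids[1:5], ids, ev, n_perm = 99L, seed = 2L)$null_values)
})

test_that("mean TE distance evaluator matches brute force and drives the permutation test", {
  set.seed(61)
  genes <- rand_genes(60, max_pos = 40000L)
  tes <- rand_intervals(40, max_pos = 42000L, max_len = 1500L)
  ev <- evaluator_mean_distance(genes, tes)
  expect_equal(ev(genes$gene_id), mean(bf_nearest(genes, tes), na.rm = TRUE))
  expect_equal(as.numeric(mean_te_distance(genes, tes)),
               mean(bf_nearest(genes, tes), na.rm = TRUE))
  two <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        start = c(0L, 1000L), end = c(100L, 1100L), strand = "+")
  tt <- tibble::tibble(chrom = "chr1", start = c(200L, 1400L), end = c(210L, 1410L))
  expect_equal(as.numeric(mean_te_distance(two, tt)), mean(c(100, 300)))
})

test_that("TSS-adjacent gene subsets are called closer to TEs by permutation", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_chrom = 2L, chrom_length = 5e6, n_genes = 600L,
                      n_tes = 900L, te_near_gene_prob = 0.3, n_clusters = 0L,
                      cluster_size = 0L, seed = 700L + s)
    ann <- simulate_annotation(cfg)
    ev <- evaluator_mean_distance(ann$genes, filter_te_annotation(ann$tes))
    res <- permutation_test(ann$truth$tss500_genes, ann$genes$gene_id, ev,
                            n_perm = 200L, seed = s)
    if (res$alternative == "less" && res$p <= 0.005) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("flank methylation evaluator matches a per-position brute force", {
  set.seed(62)
  genes <- rand_genes(20, chroms = "chr1", max_pos = 30000L)
  genes$start <- genes$start + 3000L; genes$end <- genes$end + 3000L
  pos <- sort(sample(0:40000, 3000))
  track <- tibble::tibble(chrom = "chr1", pos = pos,
                          level = runif(length(pos)))
  for (side in c("upstream", "downstream", "both")) {
    got <- mean_flank_methylation(genes, track, flank = 1000L, side = side)
    # brute force: per gene, scan every track position
    per_gene <- vapply(seq_len(nrow(genes)), function(i) {
      tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
      tts <- if (genes$strand[i] == "+") genes$end[i] - 1L else genes$start[i]
      off_up <- if (genes$strand[i] == "+") pos - tss else tss - pos
      off_dn <- if (genes$strand[i] == "+") pos - tts else tts - pos
      keep <- switch(side,
        upstream = off_up >= -1000 & off_up <= -1,
        downstream = off_dn >= 1 & off_dn <= 1000,
        both = (off_up >= -1000 & off_up <= -1) | (off_dn >= 1 & off_dn <= 1000))
      if (!any(keep)) NA_real_ else mean(track$level[keep])
    }, double(1))
    expect_equal(as.numeric(got), mean(per_gene, na.rm = TRUE), tolerance = 1e-12)
  }
  # constant track -> constant evaluator
  const <- tibble::tibble(chrom = "chr1", pos = seq(0L, 40000L, 10L), level = 0.8)
  expect_equal(as.numeric(mean_flank_methylation(genes, const, 1000L)), 0.8)
})

test_that("metaplot localises an injected mCHH island and mirrors under reflection", {
  ds <- simulate_dataset(sim_config(n_chrom = 2L, chrom_length = 1e6,
                                    n_genes = 120L, n_tes = 150L, n_sirna = 50L,
                                    n_clusters = 0L, cluster_size = 0L,
                                    chh_island_frac = 1, seed = 63L))
  chh <- ds$methylation[ds$methylation$context == "CHH", ]
  prof <- flank_methylation_profile(ds$genes, chh, flank = 1000L, window = 100L)
  up <- prof[prof$side == "upstream", ]
  peak <- up$window_index[up$mean_level > 0.3 & !is.na(up$mean_level)]
  expect_setequal(peak, c(-6L, -5L))
  background <- up$mean_level[!up$window_index %in% c(-6L, -5L)]
  expect_true(all(background < 0.2, na.rm = TRUE))

  # strand reflection of all inputs leaves the curve unchanged
  L <- 1e6
  mirror <- function(d, s, e) {
    d2 <- d; d2$start <- L - d[[e]]; d2$end <- L - d[[s]]; d2
  }
  g2 <- ds$genes; g2$start <- L - ds$genes$end; g2$end <- L - ds$genes$start
  g2$strand <- ifelse(ds$genes$strand == "+", "-", "+")
  chh2 <- chh; chh2$pos <- as.integer(L - 1L - chh$pos)
  prof2 <- flank_methylation_profile(g2, chh2, flank = 1000L, window = 100L)
  expect_equal(prof2, prof)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(64)
  ids <- sprintf("g%03d", 1:400)
  n_rep <- 300L
  hits <- 0L
  for (r in seq_len(n_rep)) {
    score <- setNames(rexp(400), ids)
    ev <- function(x) mean(score[x])
    res <- permutation_test(sample(ids, 50), ids, ev, n_perm = 99L,
                            seed = 3000L + r)
    # the alternative is chosen adaptively, so calibration is asserted on
    # directional calls: P(p <= 0.05 and "greater") is nominally 0.05
    if (res$p <= 0.05 && res$alternative == "greater") hits <- hits + 1L
  }
  rate <- hits / n_rep
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("directional methylation enrichment of flagged bins is recovered", {
  set.seed(65)
  ok <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_chrom = 2L, chrom_length = 1e6, n_genes = 150L,
                      n_tes = 200L, n_sirna = 50L, n_clusters = 0L,
                      cluster_size = 0L, chh_island_frac = 0.3,
                      seed = 800L + s)
    ds <- simulate_dataset(cfg)
    chh <- ds$methylation[ds$methylation$context == "CHH", ]
    ev <- evaluator_mean_methylation(ds$genes, chh, flank = 1000L,
                                     side = "upstream")
    flagged <- ds$truth$chh_island_genes
    res <- permutation_test(flagged, ds$genes$gene_id, ev, n_perm = 200L,
                            seed = s)
    # a uniform draw from the universe should stay near the null mean (the
    # complement of the flagged set would itself be significantly depleted)
    ctrl <- permutation_test(
      sample(ds$genes$gene_id, length(flagged)),
      ds$genes$gene_id, ev, n_perm = 200L, seed = s)
    if (res$alternative == "greater" && res$p < 0.005 && ctrl$p > 0.005) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_seeds, 0.9)
})
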