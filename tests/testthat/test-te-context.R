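mk_te <- function(start, end, chrom = "chr1", te_class = "II", sf = "DTA") {
  tibble::tibble(te_id = sprintf("te%d", seq_along(start)), chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 te_class = te_class, superfamily = sf,
                 family = paste0(sf, "_f"))
}
mk_gene <- function(start, end, strand = "+", chrom = "chr1") {
  tibble::tibble(gene_id = sprintf("g%d", seq_along(start)), chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

test_that("TE length filter is strict per class and drops repeat records", {
  tes <- tibble::tibble(
    chrom = "chr1", start = c(0L, 0L, 0L, 0L, 0L, 0L),
    end = c(1000L, 1001L, 50L, 51L, 5000L, 300L),
    te_class = c("I", "I", "II", "II", "I", "II"),
    family = c("RLC_f", "RLC_f", "DTA_f", "DTA_f", "RLG_f", "trf"))
  kept <- filter_te_annotation(tes)
  expect_equal(kept$end, c(1001L, 51L, 5000L))   # class I 1000 dropped, 1001 kept; II 50 dropped, 51 kept
  expect_error(filter_te_annotation(dplyr::mutate(tes, te_class = "x")), "te_class")
})

test_that("gene TE-context flags are strand-aware and non-exclusive", {
  plus <- mk_gene(5000, 8000, "+")
  f1 <- classify_gene_te_context(plus, mk_te(4200, 4450))
  expect_true(f1$upstream_1kb)
  expect_false(f1$body || f1$downstream_1kb || f1$tss_500)

  minus <- mk_gene(5000, 8000, "-")       # TSS at 7999
  f2 <- classify_gene_te_context(minus, mk_te(8600, 8900))
  expect_true(f2$upstream_1kb)
  expect_false(f2$body || f2$downstream_1kb || f2$tss_500)
  # a TE reaching into the oriented [TSS-500, TSS+500) window sets tss_500 too
  f2b <- classify_gene_te_context(minus, mk_te(8200, 8600))
  expect_true(f2b$upstream_1kb && f2b$tss_500)

  f3 <- classify_gene_te_context(plus, mk_te(4700, 5300))
  expect_true(f3$upstream_1kb && f3$body && f3$tss_500)
  expect_false(f3$downstream_1kb)
})

test_that("context flags survive translation and strand reflection", {
  set.seed(41)
  for (rep in 1:10) {
    genes <- rand_genes(15, chroms = "chr1", max_pos = 50000L)
    genes$start <- genes$start + 2000L; genes$end <- genes$end + 2000L
    tes <- mk_te(sample(52000, 30), 0)
    tes$end <- tes$start + sample(60:2000, 30, replace = TRUE)
    base <- classify_gene_te_context(genes, tes)

    shift <- function(d, by) dplyr::mutate(d, start = start + by, end = end + by)
    trans <- classify_gene_te_context(shift(genes, 977L), shift(tes, 977L))
    expect_equal(trans, base)

    L <- 200000L
    mirror <- function(d) dplyr::mutate(d, start2 = L - end, end = L - start,
                                        start = start2, start2 = NULL)
    g2 <- mirror(genes); g2$strand <- ifelse(genes$strand == "+", "-", "+")
    refl <- classify_gene_te_context(g2, mirror(tes))
    expect_equal(refl$upstream_1kb, base$upstream_1kb)
    expect_equal(refl$body, base$body)
    expect_equal(refl$downstream_1kb, base$downstream_1kb)
    expect_equal(refl$tss_500, base$tss_500)
    expect_equal(refl$nearest_te_distance, base$nearest_te_distance)
  }
})

test_that("nearest-TE distance matches the all-pairs brute force", {
  g <- mk_gene(c(0, 0), c(100, 100))
  g$gene_id <- c("a", "b"); g$chrom <- c("chr1", "chr1")
  inside <- nearest_te_distance(mk_gene(1000, 2000), mk_te(1200, 1300))
  expect_equal(inside$nearest_te_distance, 0)
  two <- nearest_te_distance(mk_gene(0, 100), mk_te(c(200, 1000), c(300, 1100)))
  expect_equal(two$nearest_te_distance, 100)
  set.seed(42)
  for (rep in 1:5) {
    genes <- rand_genes(100, max_pos = 20000L)
    tes <- rand_intervals(100, max_pos = 22000L, max_len = 1500L)
    got <- nearest_te_distance(genes, tes)$nearest_te_distance
    expect_equal(got, bf_nearest(genes, tes))
  }
})

test_that("a TE across the TSS window implies a short nearest distance", {
  set.seed(43)
  for (rep in 1:10) {
    genes <- rand_genes(30, max_pos = 60000L)
    genes$start <- genes$start + 1000L; genes$end <- genes$end + 1000L
    tes <- rand_intervals(60, max_pos = 65000L, max_len = 1200L)
    fl <- classify_gene_te_context(genes, tes)
    hit <- which(fl$tss_500)
    expect_true(all(fl$nearest_te_distance[hit] <= 500))
  }
})

test_that("distance-binned expression uses (lo, hi] bins with body overlap at 0", {
  d <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                      nearest_te_distance = c(0, 1, 500, 501))
  ex <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       fpkm_wt = c(1, 2, 4, 8), fpkm_mut = c(2, 4, 8, 16))
  prof <- distance_expression_profile(d, ex)
  wt <- prof[prof$genotype == "wt", ]
  expect_equal(wt$n[wt$bin == 0], 1L)
  expect_equal(wt$n[wt$bin == 1], 2L)       # distances 1 and 500 share bin 1
  expect_equal(wt$n[wt$bin == 2], 1L)       # 501 opens bin 2
  expect_equal(wt$mean_fpkm[wt$bin == 1], 3)
  all0 <- distance_expression_profile(
    tibble::tibble(gene_id = c("a", "b"), nearest_te_distance = c(0, 0)), ex)
  expect_equal(unique(all0$bin), 0L)
})

test_that("mutant/wild-type ratio decays with distance when the effect is TSS-proximal", {
  cfg <- sim_config(n_chrom = 2L, chrom_length = 5e6, n_genes = 800L,
                    n_tes = 1200L, te_effect_log2 = 1, n_clusters = 0L,
                    cluster_size = 0L, zero_rate_wt = 0, zero_rate_mut = 0,
                    seed = 44L)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann$genes, ann$tes)
  nd <- nearest_te_distance(ann$genes, filter_te_annotation(ann$tes))
  prof <- distance_expression_profile(nd, ex$expression)
  ratio_at <- function(b) {
    w <- prof[prof$bin == b, ]
    w$mean_fpkm[w$genotype == "mut"] / w$mean_fpkm[w$genotype == "wt"]
  }
  near <- ratio_at(1)
  far <- prof |>
    dplyr::filter(bin >= 4, n > 5) |>
    tidyr::pivot_wider(id_cols = "bin", names_from = "genotype",
                       values_from = "mean_fpkm") |>
    dplyr::summarise(r = mean(mut / wt))
  expect_gt(near, far$r)
})

test_that("TE-insertion frequency table reproduces printed percentages", {
  # category counts taken from a published frequency table
  flags <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:39656),
    upstream_1kb = c(rep(TRUE, 1935), rep(FALSE, 12190 - 1935),
                     rep(TRUE, 1233), rep(FALSE, 7175 - 1233),
                     rep(TRUE, 5170), rep(FALSE, 20291 - 5170)),
    tss_500 = c(rep(TRUE, 828), rep(FALSE, 12190 - 828),
                rep(TRUE, 557), rep(FALSE, 7175 - 557),
                rep(TRUE, 3095), rep(FALSE, 20291 - 3095)))
  cats <- tibble::tibble(
    gene_id = flags$gene_id,
    category = rep(c("SUB1", "SUB2", "Non-syntenic"), c(12190, 7175, 20291)))
  tab <- te_frequency_table(flags, cats)
  get <- function(cat, col) tab[[col]][tab$category == cat]
  expect_equal(get("SUB1", "pct_upstream_1kb"), 15.87)
  expect_equal(get("SUB2", "pct_upstream_1kb"), 17.18)
  expect_equal(get("Non-syntenic", "pct_upstream_1kb"), 25.48)
  expect_equal(get("total", "pct_upstream_1kb"), 21.03)
  expect_equal(get("SUB1", "pct_tss_500"), 6.79)
  expect_equal(get("SUB2", "pct_tss_500"), 7.76)
  expect_equal(get("Non-syntenic", "pct_tss_500"), 15.25)
  expect_equal(get("total", "pct_tss_500"), 11.30)
  none <- te_frequency_table(
    tibble::tibble(gene_id = "a", upstream_1kb = FALSE, tss_500 = FALSE),
    tibble::tibble(gene_id = "a", category = "x"))
  expect_equal(none$pct_upstream_1kb[none$category == "x"], 0)
})

test_that("TE-transcript classification applies the strict bit-score/coverage rules", {
  hits <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    bit_score = c(600, 300, 100, 501, 500, NA),
    coverage = c(0.55, 0.10, 0.10, 0.50, 0.55, NA))
  k <- classify_te_transcript(hits)
  expect_equal(k$klass[k$transcript_id == "t1"], "HC_TE")
  expect_equal(k$klass[k$transcript_id == "t2"], "PR_TE")   # bit > 250 suffices
  expect_equal(k$klass[k$transcript_id == "t3"], "NON_TE")
  expect_equal(k$klass[k$transcript_id == "t4"], "PR_TE")   # coverage not > 0.5
  expect_equal(k$klass[k$transcript_id == "t5"], "PR_TE")   # bit not > 500
  expect_equal(k$klass[k$transcript_id == "t6"], "NON_TE")  # no hit
  expect_error(classify_te_transcript(dplyr::mutate(hits, coverage = 2)),
               "coverage")
  multi <- tibble::tibble(transcript_id = "t", bit_score = c(600, 600, 200),
                          coverage = c(0.2, 0.6, 0.9),
                          subject_id = c("b", "a", "c"))
  expect_equal(classify_te_transcript(multi)$klass, "HC_TE")  # best hit 600/0.6
})
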