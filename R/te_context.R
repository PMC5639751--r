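# oriented windows around a gene, 0-based half-open genomic coordinates.
# "upstream" means 5' of the gene: for a - strand gene the upstream 1-kb
# window lies to the genomic right of its TSS (the rightmost gene base).
gene_windows <- function(genes, flank = 1000L, tss_halfwidth = 500L) {
  check_intervals(genes, "genes", strand_required = TRUE)
  tss <- tss_of(genes$start, genes$end, genes$strand)
  plus <- genes$strand == "+"
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    up_start = pmax(0L, ifelse(plus, genes$start - flank, genes$end)),
    up_end = ifelse(plus, genes$start, genes$end + flank),
    body_start = genes$start,
    body_end = genes$end,
    down_start = pmax(0L, ifelse(plus, genes$end, genes$start - flank)),
    down_end = ifelse(plus, genes$end + flank, genes$start),
    # oriented offsets [-w, +w) about the TSS: genomic [TSS-w, TSS+w) on the
    # + strand, [TSS-w+1, TSS+w+1) on the - strand (exact mirror image)
    tss5_start = pmax(0L, tss - tss_halfwidth + ifelse(plus, 0L, 1L)),
    tss5_end = tss + tss_halfwidth + ifelse(plus, 0L, 1L)
  )
}

#' Filter a TE annotation to informative elements
#'
#' Keeps class I retroelements longer than 1 kb and class II DNA elements
#' longer than 50 bp (strict inequalities). Low-complexity and tandem
#' repeat records (family `dust` or `trf`) are dropped when labelled.
#'
#' @param tes TE tibble with `chrom`, `start`, `end`, `te_class` in
#'   `{"I", "II"}` and optionally `family`.
#' @return The filtered tibble.
#' @export
filter_te_annotation <- function(tes) {
  check_intervals(tes, "tes")
  stopifnot_cols(tes, "te_class", "tes")
  if (any(!tes$te_class %in% c("I", "II"))) {
    abort("filter_te_annotation: te_class must be 'I' or 'II'")
  }
  if ("family" %in% names(tes)) {
    tes <- filter(tes, !tolower(.data$family) %in% c("dust", "trf"))
  }
  len <- tes$end - tes$start
  filter(tes, (.data$te_class == "I" & len > 1000) |
           (.data$te_class == "II" & len > 50))
}

#' Classify genes by TE context
#'
#' Strand-aware flags for a TE overlapping the 1-kb upstream flank of the
#' TSS, the gene body, the 1-kb downstream flank of the TTS, or the
#' oriented TSS -500/+500 bp window. The classes are not exclusive: one
#' element can set two or three flags. Flank windows extending past the
#' chromosome start are clipped at 0.
#'
#' @param genes Stranded gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param tes Filtered TE tibble (see [filter_te_annotation()]).
#' @return Tibble with one row per gene: `gene_id`, logical `upstream_1kb`,
#'   `body`, `downstream_1kb`, `tss_500`, plus `nearest_te_distance` (bp;
#'   `NA` if the chromosome carries no TE) and `nearest_te_superfamily`.
#' @export
classify_gene_te_context <- function(genes, tes) {
  w <- gene_windows(genes)
  flag <- function(ws, we) {
    win <- tibble(chrom = w$chrom, start = ws, end = we)
    ok <- win$start < win$end
    out <- rep(FALSE, nrow(win))
    if (any(ok) && nrow(tes) > 0) {
      hits <- interval_intersect(win[ok, ], tes)
      out[which(ok)[unique(hits$idx_a)]] <- TRUE
    }
    out
  }
  nd <- nearest_te_distance(genes, tes)
  tibble(
    gene_id = w$gene_id,
    upstream_1kb = flag(w$up_start, w$up_end),
    body = flag(w$body_start, w$body_end),
    downstream_1kb = flag(w$down_start, w$down_end),
    tss_500 = flag(w$tss5_start, w$tss5_end)
  ) |>
    left_join(nd, by = "gene_id")
}

#' Nearest-TE distance per gene
#'
#' Edge-to-edge gap between the gene body and its closest TE on the same
#' chromosome (0 when a TE overlaps or abuts the body). Genes on a
#' chromosome without any TE get `NA`.
#'
#' @param genes Gene tibble.
#' @param tes TE tibble (optionally with `superfamily`).
#' @return Tibble `gene_id`, `nearest_te_distance`, `nearest_te_superfamily`.
#' @export
nearest_te_distance <- function(genes, tes) {
  check_intervals(genes, "genes")
  out <- tibble(gene_id = genes$gene_id,
                nearest_te_distance = NA_real_,
                nearest_te_superfamily = NA_character_)
  if (nrow(tes) == 0 || nrow(genes) == 0) return(out)
  hits <- GenomicRanges::distanceToNearest(as_granges(genes), as_granges(tes),
                                           ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  out$nearest_te_distance[qi] <- as.numeric(S4Vectors::mcols(hits)$distance)
  if ("superfamily" %in% names(tes)) {
    out$nearest_te_superfamily[qi] <- tes$superfamily[S4Vectors::subjectHits(hits)]
  }
  out
}

#' Mean expression as a function of distance to the nearest TE
#'
#' Bin 0 holds genes whose body overlaps a TE (distance 0); bin k holds
#' distances in `((k-1) * bin_width, k * bin_width]`. Per bin and genotype
#' the arithmetic mean FPKM and its standard error are reported.
#'
#' @param distances Tibble `gene_id`, `nearest_te_distance` (NA rows are
#'   dropped).
#' @param expression Filtered expression tibble with `fpkm_<genotype>`
#'   columns.
#' @param bin_width Distance bin width in bp (default 500).
#' @return Tibble `bin`, `genotype`, `n`, `mean_fpkm`, `se_fpkm` (mean is
#'   `NA` for empty bins).
#' @export
distance_expression_profile <- function(distances, expression, bin_width = 500L) {
  stopifnot_cols(distances, c("gene_id", "nearest_te_distance"), "distances")
  fpkm_cols <- grep("^fpkm_", names(expression), value = TRUE)
  if (length(fpkm_cols) == 0) abort("distance_expression_profile: no fpkm_ columns")
  d <- distances |>
    filter(!is.na(.data$nearest_te_distance)) |>
    mutate(bin = ifelse(.data$nearest_te_distance == 0, 0L,
                        as.integer(ceiling(.data$nearest_te_distance / bin_width))))
  long <- d |>
    dplyr::inner_join(expression, by = "gene_id") |>
    tidyr::pivot_longer(all_of(fpkm_cols), names_to = "genotype",
                        names_prefix = "fpkm_", values_to = "fpkm")
  grid <- tidyr::expand_grid(bin = seq(0L, max(c(0L, d$bin))),
                             genotype = sub("^fpkm_", "", fpkm_cols))
  long |>
    group_by(.data$bin, .data$genotype) |>
    summarise(n = dplyr::n(), mean_fpkm = mean(.data$fpkm),
              se_fpkm = sd(.data$fpkm) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::right_join(grid, by = c("bin", "genotype")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    arrange(.data$bin, .data$genotype)
}

#' TE-insertion frequency table by gene category
#'
#' For each gene category: number of genes, number and percentage with a
#' TE in the 1-kb upstream flank, and number and percentage with a TE
#' across the TSS -500/+500 bp window. Percentages are rounded half-up to
#' two decimals, matching printed frequency tables.
#'
#' @param flags Context flags from [classify_gene_te_context()].
#' @param categories Tibble `gene_id`, `category`.
#' @return Tibble with one row per category plus a `total` row.
#' @export
te_frequency_table <- function(flags, categories) {
  stopifnot_cols(flags, c("gene_id", "upstream_1kb", "tss_500"), "flags")
  stopifnot_cols(categories, c("gene_id", "category"), "categories")
  joined <- dplyr::inner_join(categories, flags, by = "gene_id")
  per_cat <- joined |>
    group_by(.data$category) |>
    summarise(n_genes = dplyr::n(),
              n_upstream_1kb = sum(.data$upstream_1kb),
              n_tss_500 = sum(.data$tss_500), .groups = "drop")
  total <- joined |>
    summarise(category = "total", n_genes = dplyr::n(),
              n_upstream_1kb = sum(.data$upstream_1kb),
              n_tss_500 = sum(.data$tss_500))
  bind_rows(per_cat, total) |>
    mutate(
      pct_upstream_1kb = ifelse(.data$n_genes > 0,
                                round_half_up(100 * .data$n_upstream_1kb / .data$n_genes, 2),
                                NA_real_),
      pct_tss_500 = ifelse(.data$n_genes > 0,
                           round_half_up(100 * .data$n_tss_500 / .data$n_genes, 2),
                           NA_real_)
    ) |>
    select("category", "n_genes", "n_upstream_1kb", "pct_upstream_1kb",
           "n_tss_500", "pct_tss_500")
}

#' Classify transcripts as TE-related from homology-hit statistics
#'
#' High-confidence TE transcripts (`HC_TE`) require bit score > 500 and
#' aligned coverage > 50%; putative/relic TE transcripts (`PR_TE`) are the
#' remaining ones with bit score > 250 or coverage > 30%; everything else
#' (including transcripts without a hit) is `NON_TE`. When several hits are
#' given per transcript, the best hit is the highest bit score, ties broken
#' by higher coverage then lexicographic subject id.
#'
#' @param hits Tibble `transcript_id`, `bit_score`, `coverage` (fraction in
#'   `[0, 1]`; `NA` means no hit), optionally `subject_id`.
#' @return Tibble `transcript_id`, `bit_score`, `coverage`, `klass`.
#' @export
classify_te_transcript <- function(hits) {
  stopifnot_cols(hits, c("transcript_id", "bit_score", "coverage"), "hits")
  cov <- hits$coverage[!is.na(hits$coverage)]
  if (any(cov < 0 | cov > 1)) {
    abort("classify_te_transcript: coverage must lie in [0, 1]")
  }
  if (!"subject_id" %in% names(hits)) hits$subject_id <- NA_character_
  best <- hits |>
    arrange(.data$transcript_id, dplyr::desc(.data$bit_score),
            dplyr::desc(.data$coverage), .data$subject_id) |>
    group_by(.data$transcript_id) |>
    dplyr::slice(1) |>
    ungroup()
  best |>
    mutate(klass = dplyr::case_when(
      is.na(.data$bit_score) | is.na(.data$coverage) ~ "NON_TE",
      .data$bit_score > 500 & .data$coverage > 0.5 ~ "HC_TE",
      .data$bit_score > 250 | .data$coverage > 0.3 ~ "PR_TE",
      TRUE ~ "NON_TE"
    )) |>
    select("transcript_id", "bit_score", "coverage", "klass")
}
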