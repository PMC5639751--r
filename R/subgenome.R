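# subgenome category of each gene: sub1/sub2 singleton or duplicate,
# nonsyntenic, or unassigned
subgenome_category <- function(assignments) {
  stopifnot_cols(assignments, c("gene_id", "subgenome"), "assignments")
  dup <- if ("homeolog_partner" %in% names(assignments)) {
    !is.na(assignments$homeolog_partner)
  } else {
    rep(FALSE, nrow(assignments))
  }
  dplyr::case_when(
    assignments$subgenome == "sub1" & dup ~ "sub1_duplicate",
    assignments$subgenome == "sub1" ~ "sub1_singleton",
    assignments$subgenome == "sub2" & dup ~ "sub2_duplicate",
    assignments$subgenome == "sub2" ~ "sub2_singleton",
    assignments$subgenome == "nonsyntenic" ~ "nonsyntenic",
    TRUE ~ "unassigned"
  )
}

#' Subgenome partition frequencies with enrichment against a reference set
#'
#' For each named gene set, counts and percentages of subgenome-1/2
#' singletons and duplicates, nonsyntenic and unassigned genes. Syntenic
#' category percentages are computed over the genes assigned to a
#' subgenome; nonsyntenic and unassigned percentages over all genes of the
#' set (the dual-scale convention of subgenome frequency plots). Each
#' category of each set is compared against the reference set by a
#' two-sided 2x2 Fisher exact test.
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param assignments Tibble `gene_id`, `subgenome` in
#'   `{"sub1", "sub2", "nonsyntenic", "unassigned"}`, optional
#'   `homeolog_partner` (non-NA marks retained duplicates).
#' @param reference Name of the reference set (default: first).
#' @return Tibble `set`, `category`, `n`, `pct`, `fisher_p`.
#' @export
subgenome_frequency_report <- function(gene_sets, assignments,
                                       reference = names(gene_sets)[1]) {
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("subgenome_frequency_report: gene_sets must be a named list")
  }
  if (!reference %in% names(gene_sets)) {
    abort("subgenome_frequency_report: unknown reference set")
  }
  cat_of <- setNames(subgenome_category(assignments), assignments$gene_id)
  cats <- c("sub1_singleton", "sub1_duplicate", "sub2_singleton",
            "sub2_duplicate", "nonsyntenic", "unassigned")
  syntenic <- cats[1:4]
  count_set <- function(ids) {
    if (length(ids) == 0) abort("subgenome_frequency_report: empty gene set")
    miss <- setdiff(ids, names(cat_of))
    if (length(miss) > 0) {
      abort(sprintf("subgenome_frequency_report: gene(s) without assignment, e.g. %s", miss[1]))
    }
    table(factor(cat_of[ids], levels = cats))
  }
  counts <- lapply(gene_sets, count_set)
  ref_counts <- counts[[reference]]
  purrr::map_dfr(names(gene_sets), function(s) {
    ct <- counts[[s]]
    n_set <- sum(ct)
    n_assigned <- sum(ct[syntenic])
    purrr::map_dfr(cats, function(cl) {
      denom <- if (cl %in% syntenic) n_assigned else n_set
      p_fisher <- fisher.test(matrix(c(
        ct[[cl]], sum(ct) - ct[[cl]],
        ref_counts[[cl]], sum(ref_counts) - ref_counts[[cl]]
      ), nrow = 2, byrow = TRUE))$p.value
      tibble(set = s, category = cl, n = as.integer(ct[[cl]]),
             pct = if (denom > 0) 100 * ct[[cl]] / denom else NA_real_,
             fisher_p = p_fisher)
    })
  })
}

#' Classify homeolog pairs by differential-expression status
#'
#' Among retained homeolog pairs, counts those with at least one DE member
#' and splits them into subgenome-1-only, subgenome-2-only and both-DE.
#' The recessive fraction is the percentage of DE pairs driven by the
#' subgenome-2 (recessive) paralog alone, rounded half-up to one decimal.
#'
#' @param pairs Tibble `pair_id`, `gene_sub1`, `gene_sub2`; no gene may
#'   appear in two pairs.
#' @param de_genes Character vector of DE gene ids (already filtered to
#'   one direction).
#' @return One-row tibble `n_pairs_de`, `h1_only`, `h2_only`, `both`,
#'   `recessive_fraction`.
#' @export
homeolog_pair_de <- function(pairs, de_genes) {
  stopifnot_cols(pairs, c("pair_id", "gene_sub1", "gene_sub2"), "pairs")
  members <- c(pairs$gene_sub1, pairs$gene_sub2)
  if (anyDuplicated(members)) {
    abort("homeolog_pair_de: a gene appears in more than one pair")
  }
  h1 <- pairs$gene_sub1 %in% de_genes
  h2 <- pairs$gene_sub2 %in% de_genes
  n_de <- sum(h1 | h2)
  if (n_de == 0) abort("homeolog_pair_de: no pair has a DE member; fraction undefined")
  h2_only <- sum(h2 & !h1)
  tibble(n_pairs_de = n_de,
         h1_only = sum(h1 & !h2),
         h2_only = h2_only,
         both = sum(h1 & h2),
         recessive_fraction = round_half_up(100 * h2_only / n_de, 1))
}

# strand-oriented flank windows used by the siRNA occupancy profile:
# upstream relative to the TSS, downstream relative to the TTS
sirna_flank_window <- function(genes, flank, side) {
  tss <- tss_of(genes$start, genes$end, genes$strand)
  tts <- tts_of(genes$start, genes$end, genes$strand)
  plus <- genes$strand == "+"
  if (side == "upstream") {
    tibble(chrom = genes$chrom,
           start = pmax(0L, ifelse(plus, tss - flank, tss + 1L)),
           end = ifelse(plus, tss, tss + flank + 1L),
           anchor = tss, plus = plus)
  } else {
    tibble(chrom = genes$chrom,
           start = pmax(0L, ifelse(plus, tts + 1L, tts - flank)),
           end = ifelse(plus, tts + flank + 1L, tts),
           anchor = tts, plus = plus)
  }
}

#' Per-position siRNA-locus occupancy over gene flanks
#'
#' For each strand-oriented offset in `[-flank, -1]` relative to the TSS
#' (upstream) and `[+1, +flank]` relative to the TTS (downstream), the
#' fraction of genes whose flank base at that offset is covered by at
#' least one siRNA locus (per-position coverage semantics, not locus
#' counts).
#'
#' @param genes Non-empty stranded gene tibble (one group; call per group
#'   to compare gene classes).
#' @param sirna siRNA locus tibble (`chrom`, `start`, `end`).
#' @param flank Flank width in bp (default 1000).
#' @return Tibble `side`, `offset`, `fraction`.
#' @export
sirna_flank_occupancy <- function(genes, sirna, flank = 1000L) {
  check_intervals(genes, "genes", strand_required = TRUE)
  if (nrow(genes) == 0) abort("sirna_flank_occupancy: empty gene group")
  if (flank <= 0) abort("sirna_flank_occupancy: flank must be positive")
  one_side <- function(side) {
    win <- sirna_flank_window(genes, flank, side)
    offsets <- if (side == "upstream") seq(-flank, -1L) else seq(1L, flank)
    counts <- numeric(flank)
    if (nrow(sirna) > 0) {
      hits <- interval_intersect(select(win, "chrom", "start", "end"), sirna)
      covered <- purrr::map_dfr(seq_len(nrow(hits)), function(h) {
        i <- hits$idx_a[h]; j <- hits$idx_b[h]
        pos <- seq(max(win$start[i], sirna$start[j]),
                   min(win$end[i], sirna$end[j]) - 1L)
        off <- if (win$plus[i]) pos - win$anchor[i] else win$anchor[i] - pos
        tibble(gene = i, off = off)
      })
      if (nrow(covered) > 0) {
        # a gene covered by two loci at one offset counts once
        covered <- distinct(covered)
        tab <- covered |> count(.data$off)
        counts[match(tab$off, offsets)] <- tab$n
      }
    }
    tibble(side = side, offset = offsets, fraction = counts / nrow(genes))
  }
  bind_rows(one_side("upstream"), one_side("downstream"))
}

#' Flag genes with an siRNA locus near the TSS
#'
#' A gene is flagged when at least one siRNA locus overlaps its oriented
#' `[TSS - within, TSS + within)` window. When a designated subset of
#' loci (e.g. loci down-regulated in the mutant) is supplied, a second
#' flag marks overlap with that subset.
#'
#' @param genes Stranded gene tibble.
#' @param sirna siRNA locus tibble with `locus_id`.
#' @param within Half-width of the TSS window in bp (default 1000).
#' @param down_loci Optional character vector of `locus_id`s forming the
#'   designated subset.
#' @return Tibble `gene_id`, `sirna_associated`, and `down_locus_associated`
#'   when `down_loci` is given.
#' @export
sirna_association_flags <- function(genes, sirna, within = 1000L,
                                    down_loci = NULL) {
  check_intervals(genes, "genes", strand_required = TRUE)
  if (within <= 0) abort("sirna_association_flags: within must be positive")
  tss <- tss_of(genes$start, genes$end, genes$strand)
  plus <- genes$strand == "+"
  # oriented offsets [-within, +within): exact mirror image across strands
  win <- tibble(chrom = genes$chrom,
                start = pmax(0L, tss - within + ifelse(plus, 0L, 1L)),
                end = tss + within + ifelse(plus, 0L, 1L))
  flag_against <- function(loci) {
    out <- rep(FALSE, nrow(genes))
    if (nrow(loci) > 0) {
      hits <- interval_intersect(win, loci)
      out[unique(hits$idx_a)] <- TRUE
    }
    out
  }
  out <- tibble(gene_id = genes$gene_id,
                sirna_associated = flag_against(sirna))
  if (!is.null(down_loci)) {
    stopifnot_cols(sirna, "locus_id", "sirna")
    out$down_locus_associated <-
      flag_against(sirna[sirna$locus_id %in% down_loci, ])
  }
  out
}
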