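#' Simulation configuration for the synthetic toy dataset
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. The defaults encode the study conditions the pipeline is
#' exercised under: a two-chromosome 10-Mb toy genome, a TE placed at 66%
#' of gene transcription start sites, a 20-fold asymmetry in
#' zero-expression rates between wild type and mutant, a one-log2-unit
#' multiplicative up-shift in the mutant at genes carrying a TSS-proximal
#' TE, clustered up-regulated genes, siRNA loci enriched upstream of
#' subgenome-2 genes, high CG/CHG methylation inside TE bodies with sharp
#' CHH islands in gene upstream flanks, and genome transcribed fractions of
#' 8.45% (wild type) and 8.90% (mutant) - the published uniquely-mapped
#' coverage fractions.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes,n_tes,n_sirna Feature counts.
#' @param te_near_gene_prob Per-gene probability of carrying a dedicated TE
#'   insertion near its TSS (background TEs are kept clear of TSS windows so
#'   the realised per-gene fraction is binomial around this value).
#' @param frac_sub1,frac_sub2,frac_nonsyntenic Gene-category proportions;
#'   must sum to at most 1 (remainder is left unassigned).
#' @param zero_rate_wt,zero_rate_mut Per-genotype probability that a gene's
#'   FPKM is zeroed.
#' @param baseline_log2fpkm_mean,baseline_log2fpkm_sd Gene-level log2-FPKM
#'   distribution (log-normal expression).
#' @param noise_log2_sd Per-genotype log2 noise so the two genotypes are
#'   identical in law but not identical numbers under the null.
#' @param te_effect_log2 Additive log2 up-shift applied in the mutant to
#'   genes with a TE within +/-500 bp of the TSS.
#' @param n_clusters,cluster_size Clustered up-regulated gene structure.
#' @param cluster_effect_log2 Log2 up-shift applied in the mutant to
#'   cluster-member genes.
#' @param sirna_sub2_bias Sampling weight of subgenome-2 genes when placing
#'   siRNA loci upstream of genes (1 = no bias).
#' @param meth_cg_te,meth_chg_te CG/CHG methylation level inside TE bodies.
#' @param meth_chh_island CHH level of the injected mCHH islands
#'   (oriented offsets -600..-401 bp upstream of the TSS).
#' @param chh_island_frac Fraction of genes receiving an mCHH island.
#' @param meth_background Background methylation level outside TE bodies
#'   and islands (all contexts).
#' @param transcribed_frac_wt,transcribed_frac_mut Target genome fractions
#'   covered by >= 2 alignment footprints per genotype.
#' @param seed Integer RNG seed; the whole dataset is deterministic in it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L,
                       chrom_length = 5e6,
                       n_genes = 1000L,
                       n_tes = 2000L,
                       n_sirna = 600L,
                       te_near_gene_prob = 0.66,
                       frac_sub1 = 0.30,
                       frac_sub2 = 0.18,
                       frac_nonsyntenic = 0.52,
                       zero_rate_wt = 0.02,
                       zero_rate_mut = 0.001,
                       baseline_log2fpkm_mean = 1.5,
                       baseline_log2fpkm_sd = 2,
                       noise_log2_sd = 0.25,
                       te_effect_log2 = 1,
                       n_clusters = 20L,
                       cluster_size = 5L,
                       cluster_effect_log2 = 2,
                       sirna_sub2_bias = 2,
                       meth_cg_te = 0.9,
                       meth_chg_te = 0.7,
                       meth_chh_island = 0.6,
                       chh_island_frac = 0.5,
                       meth_background = 0.05,
                       transcribed_frac_wt = 0.0845,
                       transcribed_frac_mut = 0.0890,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(te_near_gene_prob, zero_rate_wt, zero_rate_mut, chh_island_frac,
             meth_cg_te, meth_chg_te, meth_chh_island, meth_background,
             transcribed_frac_wt, transcribed_frac_mut,
             frac_sub1, frac_sub2, frac_nonsyntenic)
  if (any(probs < 0 | probs > 1)) abort("sim_config: probabilities must lie in [0, 1]")
  if (frac_sub1 + frac_sub2 + frac_nonsyntenic > 1 + 1e-12) {
    abort("sim_config: gene-category fractions must sum to at most 1")
  }
  if (chrom_length <= 0 || n_chrom < 1) abort("sim_config: genome dimensions must be positive")
  if (sirna_sub2_bias <= 0) abort("sim_config: sirna_sub2_bias must be positive")
  structure(cfg, class = "sim_config")
}

# gene slot grid: one gene per 10-kb slot, placed 3 kb into the slot, so
# 1-kb flank windows of distinct genes can never touch
.gene_slot <- 10000L
.gene_margin <- 3000L
.footprint_len <- 50L

sim_genome <- function(config) {
  tibble(chrom = paste0("chr", seq_len(config$n_chrom)),
         length = as.integer(config$chrom_length))
}

# TE overlaps the +/-1 kb neighbourhood of a TSS point
.near_tss <- function(te_start, te_end, tss, within = 1000L) {
  te_start < tss + within + 1L & te_end > tss - within
}

# genes whose symmetric TSS +/-500 bp window overlaps a TE
.tss500_flags <- function(genes, tes, tss) {
  win <- tibble(chrom = genes$chrom, start = pmax(0L, tss - 500L),
                end = tss + 500L)
  hits <- interval_intersect(win, tes)
  seq_len(nrow(genes)) %in% hits$idx_a
}

#' Simulate gene, TE and siRNA-locus annotations
#'
#' Genes are placed non-overlapping on a 10-kb slot grid with random
#' strands; `n_clusters` runs of `cluster_size` consecutive slots are
#' reserved as injected gene clusters (recorded in the `cluster` column).
#' Each gene independently receives a dedicated TE insertion near its TSS
#' with probability `te_near_gene_prob`; the remaining TEs are placed
#' uniformly but rejected out of all TSS +/-1 kb neighbourhoods, so the
#' per-gene near-TE fraction is binomial around the target. siRNA loci are
#' placed inside 1-kb upstream flanks of genes sampled with weight
#' `sirna_sub2_bias` for subgenome-2 genes.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `genes`, `tes`, `sirna`, the `genome` table
#'   and a `truth` record (cluster members, TSS-proximal TE genes, siRNA
#'   target genes).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  with_seed(config$seed, {
    slots_per_chrom <- config$chrom_length %/% .gene_slot
    slots <- tibble(
      chrom = rep(genome$chrom, each = slots_per_chrom),
      slot = rep(seq_len(slots_per_chrom) - 1L, times = config$n_chrom)
    )
    if (nrow(slots) < config$n_genes) {
      abort("simulate_annotation: genome too small to place requested genes without overlap")
    }

    # reserve cluster runs of consecutive slots, then fill the rest at random
    n_clustered <- config$n_clusters * config$cluster_size
    if (n_clustered > config$n_genes) {
      abort("simulate_annotation: n_clusters * cluster_size exceeds n_genes")
    }
    used <- rep(FALSE, nrow(slots))
    cluster_of <- rep(NA_integer_, nrow(slots))
    if (config$n_clusters > 0 && config$cluster_size > 0) {
      for (cl in seq_len(config$n_clusters)) {
        placed <- FALSE
        for (try in 1:1000) {
          i <- sample.int(nrow(slots) - config$cluster_size + 1L, 1L)
          run <- i:(i + config$cluster_size - 1L)
          same_chrom <- length(unique(slots$chrom[run])) == 1L
          if (same_chrom && !any(used[run])) {
            used[run] <- TRUE
            cluster_of[run] <- cl
            placed <- TRUE
            break
          }
        }
        if (!placed) abort("simulate_annotation: could not place gene clusters; genome too crowded")
      }
    }
    free <- which(!used)
    extra <- sample(free, config$n_genes - n_clustered)
    chosen <- c(which(used), extra)
    ord <- order(slots$chrom[chosen], slots$slot[chosen])
    chosen <- chosen[ord]

    gene_len <- sample(1000:4000, config$n_genes, replace = TRUE)
    start <- slots$slot[chosen] * .gene_slot + .gene_margin
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
      chrom = slots$chrom[chosen],
      start = as.integer(start),
      end = as.integer(start + gene_len),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      biotype = sample(c("coding", "lncRNA", "sRNA_precursor"), config$n_genes,
                       replace = TRUE, prob = c(0.8, 0.08, 0.12)),
      source = sample(c("reference", "de_novo"), config$n_genes,
                      replace = TRUE, prob = c(0.7, 0.3)),
      cluster = cluster_of[chosen]
    )

    # subgenome categories and homeolog pairing
    cat <- sample(c("sub1", "sub2", "nonsyntenic", "unassigned"),
                  config$n_genes, replace = TRUE,
                  prob = c(config$frac_sub1, config$frac_sub2,
                           config$frac_nonsyntenic,
                           max(0, 1 - config$frac_sub1 - config$frac_sub2 -
                                 config$frac_nonsyntenic)))
    genes$subgenome <- cat
    genes$homeolog_partner <- NA_character_
    s1 <- which(cat == "sub1")
    s2 <- which(cat == "sub2")
    n_pairs <- floor(0.6 * min(length(s1), length(s2)))
    if (n_pairs > 0) {
      p1 <- sample(s1, n_pairs)
      p2 <- sample(s2, n_pairs)
      genes$homeolog_partner[p1] <- genes$gene_id[p2]
      genes$homeolog_partner[p2] <- genes$gene_id[p1]
    }

    tss <- tss_of(genes$start, genes$end, genes$strand)

    # one dedicated TSS-proximal TE per flagged gene
    near_gene <- which(runif(config$n_genes) < config$te_near_gene_prob)
    if (length(near_gene) > config$n_tes) {
      abort("simulate_annotation: n_tes too small for requested te_near_gene_prob")
    }
    sf_I <- c("RLC", "RLG", "RLX", "RIL")
    sf_II <- c("DTA", "DTC", "DTH", "DTM", "DHH")
    n_bg <- config$n_tes - length(near_gene)
    te_class <- sample(c("I", "II"), config$n_tes, replace = TRUE)
    te_len <- ifelse(te_class == "I",
                     sample(1001:3000, config$n_tes, replace = TRUE),
                     sample(51:400, config$n_tes, replace = TRUE))
    superfamily <- ifelse(te_class == "I",
                          sample(sf_I, config$n_tes, replace = TRUE),
                          sample(sf_II, config$n_tes, replace = TRUE))
    te_chrom <- character(config$n_tes)
    te_start <- integer(config$n_tes)
    k <- length(near_gene)
    if (k > 0) {
      # centre within +/-400 bp of the TSS: the element always spans the
      # oriented TSS -500/+500 window, so te_near_gene_prob is also the
      # expected fraction of genes carrying the expression effect
      centre <- tss[near_gene] + sample(-400:400, k, replace = TRUE)
      st <- pmax(0L, as.integer(centre - te_len[seq_len(k)] %/% 2L))
      te_chrom[seq_len(k)] <- genes$chrom[near_gene]
      te_start[seq_len(k)] <- st
    }
    # background TEs: uniform, rejected out of every TSS +/-1 kb window
    if (n_bg > 0) {
      tss_by_chrom <- lapply(split(tss, genes$chrom), sort)
      need <- k + seq_len(n_bg)
      while (length(need) > 0) {
        ch <- sample(genome$chrom, length(need), replace = TRUE)
        st <- as.integer(floor(runif(length(need)) *
                                 (config$chrom_length - te_len[need])))
        en <- st + te_len[need]
        # TE is near a TSS iff some TSS lies in [st - 1000, en + 999]
        ok <- vapply(seq_along(need), function(i) {
          ts <- tss_by_chrom[[ch[i]]]
          is.null(ts) ||
            findInterval(en[i] + 999, ts) - findInterval(st[i] - 1001, ts) == 0
        }, logical(1))
        te_chrom[need[ok]] <- ch[ok]
        te_start[need[ok]] <- st[ok]
        need <- need[!ok]
      }
    }
    tes <- tibble(
      te_id = sprintf("te_%05d", seq_len(config$n_tes)),
      chrom = te_chrom, start = te_start,
      end = as.integer(te_start + te_len),
      strand = "*",
      te_class = te_class, superfamily = superfamily,
      family = paste0(superfamily, "_fam", sample(1:30, config$n_tes, replace = TRUE))
    )

    # siRNA loci inside 1-kb upstream flanks, sub2-weighted
    w <- ifelse(genes$subgenome == "sub2", config$sirna_sub2_bias, 1)
    target_gene <- sample.int(config$n_genes, config$n_sirna, replace = TRUE,
                              prob = w / sum(w))
    loc_len <- sample(50:150, config$n_sirna, replace = TRUE)
    off <- vapply(loc_len, function(l) sample.int(1000L - l, 1L), integer(1))
    g_tss <- tss[target_gene]
    plus <- genes$strand[target_gene] == "+"
    # oriented upstream flank is [TSS-1000, TSS) for +, [TSS+1, TSS+1001) for -
    loc_start <- ifelse(plus, g_tss - 1000L + off, g_tss + 1L + off)
    sirna <- tibble(
      locus_id = sprintf("sirna_%05d", seq_len(config$n_sirna)),
      chrom = genes$chrom[target_gene],
      start = as.integer(loc_start),
      end = as.integer(loc_start + loc_len)
    )

    # truth: which genes carry a TE across the oriented TSS +/-500 window
    tss500 <- .tss500_flags(genes, tes, tss)

    truth <- list(
      te_near_genes = genes$gene_id[near_gene],
      tss500_genes = genes$gene_id[tss500],
      cluster_genes = genes$gene_id[!is.na(genes$cluster)],
      sirna_target_genes = genes$gene_id[target_gene]
    )
    list(genome = genome, genes = genes, tes = tes, sirna = sirna, truth = truth)
  })
}

#' Simulate the two-genotype expression table
#'
#' Wild-type FPKM is log-normal: `log2 FPKM = mu_g + eps`, with gene effect
#' `mu_g ~ N(baseline_log2fpkm_mean, baseline_log2fpkm_sd)` and independent
#' per-genotype noise `eps ~ N(0, noise_log2_sd)`. The mutant adds
#' `te_effect_log2` for genes with a TE across the oriented TSS +/-500 bp
#' window and `cluster_effect_log2` for injected cluster members. Zeros are
#' injected independently per genotype at the configured rates.
#'
#' @param config A [sim_config()].
#' @param genes,tes Annotation tibbles from [simulate_annotation()].
#' @return List with the expression tibble (`gene_id`, `fpkm_wt`,
#'   `fpkm_mut`, `status_wt`, `status_mut`) and a `truth` record naming the
#'   genes that received each effect.
#' @export
simulate_expression <- function(config, genes, tes) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- nrow(genes)
    tss <- tss_of(genes$start, genes$end, genes$strand)
    tss500 <- .tss500_flags(genes, tes, tss)
    clustered <- if ("cluster" %in% names(genes)) !is.na(genes$cluster) else rep(FALSE, n)

    mu <- rnorm(n, config$baseline_log2fpkm_mean, config$baseline_log2fpkm_sd)
    shift <- config$te_effect_log2 * tss500 + config$cluster_effect_log2 * clustered
    fpkm_wt <- 2^(mu + rnorm(n, 0, config$noise_log2_sd))
    fpkm_mut <- 2^(mu + shift + rnorm(n, 0, config$noise_log2_sd))
    fpkm_wt[runif(n) < config$zero_rate_wt] <- 0
    fpkm_mut[runif(n) < config$zero_rate_mut] <- 0

    expr <- tibble(
      gene_id = genes$gene_id,
      fpkm_wt = fpkm_wt, fpkm_mut = fpkm_mut,
      status_wt = "OK", status_mut = "OK"
    )
    list(expression = expr,
         truth = list(te_effect_genes = genes$gene_id[tss500],
                      cluster_effect_genes = genes$gene_id[clustered]))
  })
}

#' Simulate per-context cytosine methylation tracks
#'
#' CG and CHG sites are laid every 20 bp inside TE bodies at the configured
#' levels; all contexts carry sparse background sites (every 200 bp) at
#' `meth_background`. CHH islands of level `meth_chh_island` are injected
#' at oriented offsets -600..-401 bp upstream of the TSS of a random
#' `chh_island_frac` fraction of genes (sites every 10 bp). A level
#' parameter of exactly 0 yields exactly-zero levels for its sites.
#'
#' @param config A [sim_config()].
#' @param genes,tes Annotation tibbles from [simulate_annotation()].
#' @return List with `track` (tibble `context`, `chrom`, `pos`, `level`)
#'   and `truth` (`chh_island_genes`, island oriented offsets).
#' @export
simulate_methylation <- function(config, genes, tes) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    genome <- sim_genome(config)
    lvl <- function(n, mean, sdv = 0.03) {
      if (mean == 0) rep(0, n) else pmin(1, pmax(0, rnorm(n, mean, sdv)))
    }
    bg <- function(context, exclude_te = FALSE) {
      pos <- unlist(lapply(genome$length, function(L) seq(0L, L - 1L, by = 200L)),
                    use.names = FALSE)
      chrom <- rep(genome$chrom, times = vapply(genome$length, function(L)
        length(seq(0L, L - 1L, by = 200L)), integer(1)))
      out <- tibble(context = context, chrom = chrom, pos = as.integer(pos),
                    level = lvl(length(pos), config$meth_background, 0.02))
      if (exclude_te && nrow(tes) > 0) {
        # TE bodies carry their own site grid at the TE-body level
        hit <- interval_intersect(
          tibble(chrom = out$chrom, start = out$pos, end = out$pos + 1L), tes)
        if (nrow(hit) > 0) out <- out[-unique(hit$idx_a), ]
      }
      out
    }
    te_sites <- function(context, mean) {
      pos <- mapply(function(s, e) seq(s, e - 1L, by = 20L),
                    tes$start, tes$end, SIMPLIFY = FALSE)
      chrom <- rep(tes$chrom, times = lengths(pos))
      pos <- unlist(pos, use.names = FALSE)
      tibble(context = context, chrom = chrom, pos = as.integer(pos),
             level = lvl(length(pos), mean))
    }
    island_genes <- genes$gene_id[runif(nrow(genes)) < config$chh_island_frac]
    gi <- genes[genes$gene_id %in% island_genes, ]
    islands <- if (nrow(gi) > 0) {
      tss <- tss_of(gi$start, gi$end, gi$strand)
      offs <- seq(-600L, -401L, by = 10L)
      pos <- lapply(seq_len(nrow(gi)), function(i) {
        if (gi$strand[i] == "+") tss[i] + offs else tss[i] - offs
      })
      chrom <- rep(gi$chrom, each = length(offs))
      pos <- unlist(pos, use.names = FALSE)
      tibble(context = "CHH", chrom = chrom, pos = as.integer(pos),
             level = lvl(length(pos), config$meth_chh_island))
    } else {
      tibble(context = character(), chrom = character(),
             pos = integer(), level = double())
    }
    # TE-body and island sites listed first so they win position collisions
    # with the sparse background grid
    track <- bind_rows(
      te_sites("CG", config$meth_cg_te), bg("CG", exclude_te = TRUE),
      te_sites("CHG", config$meth_chg_te), bg("CHG", exclude_te = TRUE),
      islands, bg("CHH")
    ) |>
      distinct(.data$context, .data$chrom, .data$pos, .keep_all = TRUE) |>
      arrange(.data$context, .data$chrom, .data$pos)
    list(track = track,
         truth = list(chh_island_genes = island_genes,
                      island_offsets = c(-600L, -401L)))
  })
}

#' Simulate alignment footprints realising a target transcribed fraction
#'
#' Places pairs of identical 50-bp footprints on a non-overlapping 50-bp
#' slot grid: the fraction of the genome covered by >= 2 footprints is then
#' exactly `50 * n_pairs / genome_size`, controlled to the target within
#' the grid granularity. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @param genome Genome tibble (`chrom`, `length`).
#' @return List with `alignments` (named list of interval tibbles, one per
#'   genotype `wt`/`mut`) and `truth` (realised covered fractions).
#' @export
simulate_alignments <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    G <- sum(genome$length)
    slots_per_chrom <- genome$length %/% .footprint_len
    total_slots <- sum(slots_per_chrom)
    one <- function(frac) {
      if (frac == 0) {
        return(list(aln = tibble(chrom = character(), start = integer(),
                                 end = integer()),
                    realized = 0))
      }
      n_pairs <- round(frac * G / .footprint_len)
      if (n_pairs > total_slots) {
        abort("simulate_alignments: target fraction infeasible at this footprint count")
      }
      pick <- sample.int(total_slots, n_pairs)
      chrom_idx <- findInterval(pick - 1L, cumsum(c(0L, slots_per_chrom)),
                                rightmost.closed = FALSE)
      within <- pick - c(0L, cumsum(slots_per_chrom))[chrom_idx] - 1L
      start <- as.integer(within * .footprint_len)
      st2 <- rep(start, 2L)
      aln <- tibble(chrom = rep(genome$chrom[chrom_idx], 2L),
                    start = st2,
                    end = st2 + .footprint_len) |>
        arrange(.data$chrom, .data$start)
      list(aln = aln, realized = n_pairs * .footprint_len / G)
    }
    wt <- one(config$transcribed_frac_wt)
    mut <- one(config$transcribed_frac_mut)
    list(alignments = list(wt = wt$aln, mut = mut$aln),
         truth = list(transcribed_frac_wt = wt$realized,
                      transcribed_frac_mut = mut$realized))
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs [simulate_annotation()], [simulate_expression()],
#' [simulate_methylation()] and [simulate_alignments()] under one config
#' and merges their truth records, so every downstream stage has a
#' parameter-recovery target computable without re-reading annotations.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_dataset` with elements `genome`,
#'   `genes`, `tes`, `sirna`, `expression`, `methylation`, `alignments`
#'   and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(config, ann$genes, ann$tes)
  meth <- simulate_methylation(config, ann$genes, ann$tes)
  aln <- simulate_alignments(config, ann$genome)
  structure(list(
    config = config,
    genome = ann$genome,
    genes = ann$genes,
    tes = ann$tes,
    sirna = ann$sirna,
    expression = expr$expression,
    methylation = meth$track,
    alignments = aln$alignments,
    truth = c(ann$truth, expr$truth, meth$truth, aln$truth)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits BED6 for genes, TEs, siRNA loci and alignments, one bedGraph per
#' methylation context, a TSV expression table and a JSON truth record, so
#' generated data round-trip through [read_annotation()].
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(dataset$genome, p("genome.tsv"))
  write_annotation(dplyr::rename(dataset$genes, name = "gene_id"),
                   p("genes.bed"), "bed")
  write_annotation(dplyr::rename(dataset$tes, name = "te_id"),
                   p("tes.bed"), "bed")
  write_annotation(dplyr::rename(dataset$sirna, name = "locus_id"),
                   p("sirna.bed"), "bed")
  readr::write_tsv(dataset$genes, p("genes.tsv"))
  readr::write_tsv(dataset$tes, p("tes.tsv"))
  for (gt in names(dataset$alignments)) {
    write_annotation(dataset$alignments[[gt]],
                     p(sprintf("alignments_%s.bed", gt)), "bed")
  }
  for (ctx in unique(dataset$methylation$context)) {
    tr <- dataset$methylation[dataset$methylation$context == ctx, ]
    readr::write_lines(paste(tr$chrom, tr$pos, tr$pos + 1L,
                             formatC(tr$level, digits = 6, format = "f"),
                             sep = "\t"),
                       p(sprintf("meth_%s.bedgraph", tolower(ctx))))
  }
  readr::write_tsv(dataset$expression, p("expression.tsv"))
  jsonlite::write_json(dataset$truth, p("truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
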