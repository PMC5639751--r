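# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-base arrays, all-pairs loops, full enumeration)
# so they share no code path with the implementation they check.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                           max_len = 100L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

rand_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  g <- rand_intervals(n, chroms, max_pos, max_len = 3000L)
  g$gene_id <- sprintf("g%03d", seq_len(n))
  g$strand <- sample(c("+", "-"), n, replace = TRUE)
  g
}

# all-pairs interval overlap (half-open)
bf_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  }
  m <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(idx_a = m[, 1], idx_b = m[, 2]),
                 idx_a, idx_b)
}

bf_gap <- function(a, b) max(0, b$start - a$end, a$start - b$end)

# per-gene nearest-TE gap by scanning every TE
bf_nearest <- function(genes, tes) {
  vapply(seq_len(nrow(genes)), function(i) {
    on <- which(tes$chrom == genes$chrom[i])
    if (length(on) == 0) return(NA_real_)
    min(vapply(on, function(j) {
      bf_gap(genes[i, ], tes[j, ])
    }, double(1)))
  }, double(1))
}

# per-base depth array count of positions covered by >= min_reads
bf_covered_bases <- function(alignments, genome, min_reads) {
  total <- 0
  for (i in seq_len(nrow(genome))) {
    depth <- integer(genome$length[i])
    on <- alignments[alignments$chrom == genome$chrom[i], ]
    for (j in seq_len(nrow(on))) {
      idx <- (on$start[j] + 1L):on$end[j]
      depth[idx] <- depth[idx] + 1L
    }
    total <- total + sum(depth >= min_reads)
  }
  total
}

# sup of |ECDF_x - ECDF_y| evaluated at every pooled point
bf_ks_d <- function(x, y) {
  Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
  pts <- sort(unique(c(x, y)))
  max(abs(Fx(pts) - Fy(pts)))
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (same "at most as probable" rule)
bf_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled sample (tie-free inputs only)
bf_mwu <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}
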