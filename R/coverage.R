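#' Down-sample an alignment set to a fixed number of records
#'
#' Uniform sample without replacement of exactly `target` records;
#' deterministic for a fixed seed. Mirrors normalising pooled libraries by
#' random down-sampling before coverage estimation.
#'
#' @param alignments Interval tibble (`chrom`, `start`, `end`).
#' @param target Number of records to keep; must not exceed `nrow(alignments)`.
#' @param seed Integer RNG seed.
#' @return A tibble that is a subset of the input rows.
#' @export
downsample_alignments <- function(alignments, target, seed = NULL) {
  check_intervals(alignments, "alignments")
  n <- nrow(alignments)
  if (target > n) abort(sprintf("downsample: target (%d) exceeds alignment count (%d)", target, n))
  if (target == n) return(alignments)
  idx <- with_seed(seed, sample.int(n, target))
  alignments[sort(idx), ]
}

#' Estimate the transcribed fraction of a genome
#'
#' Per replicate, the alignment set is down-sampled to `target` records and
#' the number of genome positions covered by at least `min_reads`
#' footprints is counted (difference-array coverage via GenomicRanges). The
#' reported `bases_covered` is the mean over replicates, rounded down to an
#' integer; the full-precision fraction is reported alongside.
#'
#' @param alignments Interval tibble of footprints.
#' @param genome Tibble (`chrom`, `length`); must cover every alignment
#'   chromosome, and no footprint may extend past its chromosome end.
#' @param min_reads Minimum per-base footprint depth to call a base
#'   transcribed (default 2).
#' @param n_replicates Number of down-sampling replicates (default 3).
#' @param target Down-sampling target; defaults to the full set.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param genotype Label carried into the report.
#' @return A list of class `coverage_report`.
#' @export
transcribed_fraction <- function(alignments, genome, min_reads = 2L,
                                 n_replicates = 3L, target = nrow(alignments),
                                 seed = 1L, genotype = "sample") {
  stopifnot_cols(genome, c("chrom", "length"), "genome")
  genome_size <- sum(as.numeric(genome$length))
  if (nrow(alignments) > 0) {
    check_intervals(alignments, "alignments")
    miss <- setdiff(unique(alignments$chrom), genome$chrom)
    if (length(miss) > 0) {
      abort(sprintf("alignments on chromosome(s) absent from genome: %s",
                    paste(miss, collapse = ", ")))
    }
    len <- setNames(genome$length, genome$chrom)
    bad <- which(alignments$end > len[alignments$chrom])
    if (length(bad) > 0) {
      abort(sprintf("alignment record %d extends beyond chromosome end", bad[1]))
    }
  }
  replicates <- vapply(seq_len(n_replicates), function(r) {
    sub <- downsample_alignments(alignments, target, seed = seed + r)
    covered_bases(sub, genome, min_reads)
  }, double(1))
  bases <- floor(mean(replicates))
  structure(list(
    genotype = genotype,
    n_alignments_used = as.integer(target),
    bases_covered = bases,
    genome_size = genome_size,
    fraction = mean(replicates) / genome_size,
    replicates = replicates,
    min_reads = as.integer(min_reads)
  ), class = "coverage_report")
}

# bases covered by >= min_reads footprints (event/difference-array algorithm
# through the coverage Rle)
covered_bases <- function(alignments, genome, min_reads) {
  if (nrow(alignments) == 0) return(0)
  gr <- as_granges(alignments, seqlengths = genome)
  cov <- GenomicRanges::coverage(gr)
  sum(vapply(cov, function(rle) {
    sum(as.numeric(S4Vectors::runLength(rle)[S4Vectors::runValue(rle) >= min_reads]))
  }, double(1)))
}

#' Build a coverage report from externally computed totals
#'
#' Wraps already-averaged covered-bp totals (e.g. published coverage
#' numbers, or counts from another tool) in a `coverage_report` so they can
#' be fed to [compare_transcribed_fraction()].
#'
#' @param genotype Label.
#' @param bases_covered Bases covered by at least `min_reads` footprints.
#' @param genome_size Genome size in bp.
#' @param min_reads Depth threshold the totals were computed at.
#' @param n_alignments_used Down-sampling target the totals were computed at.
#' @return A `coverage_report`.
#' @export
coverage_report <- function(genotype, bases_covered, genome_size,
                            min_reads = 2L, n_alignments_used = NA_integer_) {
  if (bases_covered < 0 || bases_covered > genome_size) {
    abort("coverage_report: need 0 <= bases_covered <= genome_size")
  }
  structure(list(
    genotype = genotype,
    n_alignments_used = n_alignments_used,
    bases_covered = bases_covered,
    genome_size = genome_size,
    fraction = bases_covered / genome_size,
    replicates = bases_covered,
    min_reads = as.integer(min_reads)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s: %s / %s bp covered by >= %d reads (%.4f%%)\n",
              x$genotype, format(x$bases_covered, big.mark = ","),
              format(x$genome_size, big.mark = ","), x$min_reads,
              100 * x$fraction))
  invisible(x)
}

#' Compare transcribed fractions between two genotypes
#'
#' Reports the absolute bp difference and the relative increase
#' `100 * (b - a) / a`, rounded half-up to the nearest integer percent for
#' the headline field and kept at full precision alongside.
#'
#' @param report_a,report_b `coverage_report` objects computed with an
#'   identical genome, threshold and down-sampling target.
#' @return One-row tibble with `bases_a`, `bases_b`, `diff_bp`,
#'   `relative_increase_pct`, `headline_pct`.
#' @export
compare_transcribed_fraction <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "coverage_report"),
            inherits(report_b, "coverage_report"))
  if (report_a$genome_size != report_b$genome_size ||
      report_a$min_reads != report_b$min_reads ||
      !identical(report_a$n_alignments_used, report_b$n_alignments_used)) {
    abort("compare_transcribed_fraction: reports differ in genome, threshold or target")
  }
  rel <- 100 * (report_b$bases_covered - report_a$bases_covered) /
    report_a$bases_covered
  tibble(
    genotype_a = report_a$genotype, genotype_b = report_b$genotype,
    bases_a = report_a$bases_covered, bases_b = report_b$bases_covered,
    diff_bp = report_b$bases_covered - report_a$bases_covered,
    relative_increase_pct = rel,
    headline_pct = round_half_up(rel, 0)
  )
}
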