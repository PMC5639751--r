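#' Read a genomic annotation file into a tibble of intervals
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' `start` is the first base of the feature, `end` is one past the last.
#' GFF3 input (1-based, fully closed) is converted at this boundary; BED is
#' passed through unchanged. Input record order is preserved.
#'
#' @param path Path to the annotation file.
#' @param format One of `"bed"`, `"gff3"` or `"tsv"`. BED may have 3-6
#'   columns (chrom, start, end, name, score, strand). TSV must carry a
#'   header row with at least `chrom`, `start`, `end`.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the input, `name`, `score`, `strand` (BED/GFF3) plus `source`,
#'   `type`, `attributes` for GFF3.
#' @export
read_annotation <- function(path, format = c("bed", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    check_intervals(out, what = path)
    return(as_tibble(out))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    nf <- lengths(fields)
    bad <- which(nf < 3)
    if (length(bad) > 0) {
      abort(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                    lineno[bad[1]], path))
    }
    get <- function(i, default = NA_character_) {
      vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
    }
    start <- suppressWarnings(as.integer(get(2)))
    end <- suppressWarnings(as.integer(get(3)))
    bad <- which(is.na(start) | is.na(end) | end <= start)
    if (length(bad) > 0) {
      abort(sprintf("malformed BED line %d in %s: bad coordinates",
                    lineno[bad[1]], path))
    }
    out <- tibble(
      chrom = get(1), start = start, end = end,
      name = get(4),
      score = suppressWarnings(as.double(get(5))),
      strand = ifelse(get(6) %in% c("+", "-"), get(6), "*")
    )
  } else {
    nf <- lengths(fields)
    bad <- which(nf < 9)
    if (length(bad) > 0) {
      abort(sprintf("malformed GFF3 line %d in %s: fewer than 9 fields",
                    lineno[bad[1]], path))
    }
    m <- do.call(rbind, fields)
    start1 <- suppressWarnings(as.integer(m[, 4]))
    end1 <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(start1) | is.na(end1) | end1 < start1)
    if (length(bad) > 0) {
      abort(sprintf("malformed GFF3 line %d in %s: end < start or non-numeric coordinates",
                    lineno[bad[1]], path))
    }
    out <- tibble(
      chrom = m[, 1], start = start1 - 1L, end = end1,
      name = sub('.*(?:ID|Name)=([^;]+).*', '\\1', m[, 9]),
      score = suppressWarnings(as.double(m[, 6])),
      strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
      source = m[, 2], type = m[, 3], attributes = m[, 9]
    )
  }
  check_intervals(out, what = path)
  out
}

#' Write intervals to BED6 or GFF3
#'
#' Output is sorted by (chrom, start). GFF3 output converts back to 1-based
#' inclusive coordinates, so a read/write/read round trip is the identity.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (and `source`, `type` for GFF3).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  check_intervals(x, what = "x")
  x <- arrange(x, .data$chrom, .data$start)
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), ".", x$score) else "."
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, ".")
  } else "."
  if (format == "bed") {
    lines <- paste(x$chrom, x$start, x$end, name, score, strand, sep = "\t")
  } else {
    src <- if ("source" %in% names(x)) x$source else "rddmscan"
    type <- if ("type" %in% names(x)) x$type else "feature"
    attrs <- if ("attributes" %in% names(x)) x$attributes else paste0("ID=", name)
    lines <- paste(x$chrom, src, type, x$start + 1L, x$end, score, strand,
                   ".", attrs, sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' All overlapping pairs between two interval sets
#'
#' Returns every pair `(i, j)` such that row `i` of `a` and row `j` of `b`
#' lie on the same chromosome and overlap under half-open semantics
#' (`a.start < b.end` and `b.start < a.end`); abutting intervals do not
#' overlap. The result is independent of input row order (rows are sorted
#' by `idx_a`, `idx_b`).
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return Tibble with columns `idx_a`, `idx_b` (row indices into the inputs).
#' @export
interval_intersect <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      ignore.strand = TRUE)
  tibble(idx_a = S4Vectors::queryHits(hits),
         idx_b = S4Vectors::subjectHits(hits)) |>
    arrange(.data$idx_a, .data$idx_b)
}

#' Edge-to-edge gap between intervals on the same chromosome
#'
#' The gap is `max(0, b.start - a.end, a.start - b.end)`: 0 if and only if
#' the intervals overlap or abut. Vectorised over rows; `a` and `b` are
#' recycled to a common length.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`) of equal length
#'   (or length 1).
#' @return Integer vector of gap distances in bp.
#' @export
gap_distance <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  if (any(a$chrom[ai] != b$chrom[bi])) {
    abort("gap_distance: intervals on different chromosomes (pre-filter by chrom)")
  }
  pmax(0L, b$start[bi] - a$end[ai], a$start[ai] - b$end[bi])
}
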