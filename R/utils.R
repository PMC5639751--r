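#' @importFrom rlang abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number distinct count across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom quantile sd fisher.test wilcox.test
#'   ecdf setNames
#' @importFrom utils head
NULL

# round half away from zero at d decimals (R's round() is banker's rounding;
# printed tables in this field round 0.5 up)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run expr with a local RNG state seeded from `seed`; restores caller's RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# strand-aware TSS/TTS in 0-based half-open coordinates
tss_of <- function(start, end, strand) ifelse(strand == "-", end - 1L, start)
tts_of <- function(start, end, strand) ifelse(strand == "-", start, end - 1L)

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}

check_intervals <- function(df, what = "intervals", strand_required = FALSE) {
  stopifnot_cols(df, c("chrom", "start", "end"), what)
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end) | is.na(df$chrom) |
                 df$chrom == "")
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval at row %d (need 0 <= start < end and non-empty chrom)",
                  what, bad[1]))
  }
  if (strand_required) {
    stopifnot_cols(df, "strand", what)
    if (any(!df$strand %in% c("+", "-"))) {
      abort(sprintf("%s: strand must be '+' or '-' for every record", what))
    }
  }
  invisible(df)
}

# tibble of 0-based half-open intervals -> GRanges (1-based closed)
as_granges <- function(df, seqlengths = NULL) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  sl <- NULL
  if (!is.null(seqlengths)) {
    sl <- setNames(seqlengths$length, seqlengths$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand,
    seqlengths = sl
  )
}
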