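#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_step
#'   geom_point geom_hline labs facet_wrap
#' @export
ggplot2::autoplot

#' Plot a binned expression distribution
#'
#' Histogram of log2-binned FPKM frequencies with the cumulative curve
#' overlaid, the standard presentation of expression-distribution
#' comparisons.
#'
#' @param object A `binned_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_distribution <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$bin)) +
    geom_col(aes(y = .data$frequency), fill = "grey70") +
    geom_line(aes(y = .data$cumulative), colour = "firebrick") +
    geom_point(aes(y = .data$cumulative), colour = "firebrick", size = 0.8) +
    labs(x = "log2(FPKM) bin", y = "frequency / cumulative frequency",
         title = sprintf("%d positive genes; zero fraction %.3f",
                         object$n_positive, object$zero_fraction))
}

#' Plot a permutation-test null distribution
#'
#' Null histogram with the observed value marked, the usual rendering of
#' gene-identity permutation tests.
#'
#' @param object A `perm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_result <- function(object, ...) {
  ggplot(tibble(null = object$null_values), aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    labs(x = "evaluator value under the null", y = "count",
         title = sprintf("observed %.4g, p = %.4g (%s)",
                         object$observed, object$p, object$alternative))
}

#' Plot a flanking methylation metaplot
#'
#' @param profile Tibble from [flank_methylation_profile()].
#' @param context Optional context label for the title.
#' @return A ggplot of per-window mean methylation against oriented
#'   window index (negative = upstream of the TSS, positive = downstream
#'   of the TTS).
#' @export
plot_methylation_profile <- function(profile, context = NULL) {
  ggplot(profile, aes(x = .data$window_index, y = .data$mean_level)) +
    geom_line(na.rm = TRUE) +
    geom_point(size = 0.8, na.rm = TRUE) +
    labs(x = "flank window (oriented)", y = "mean methylation level",
         title = context)
}

#' Plot siRNA-locus occupancy profiles over gene flanks
#'
#' @param profiles Tibble from [sirna_flank_occupancy()], optionally
#'   row-bound across gene groups with a `group` column.
#' @return A ggplot of per-position coverage fraction against oriented
#'   offset, faceted by flank side.
#' @export
plot_occupancy_profile <- function(profiles) {
  p <- ggplot(profiles, aes(x = .data$offset, y = .data$fraction))
  p <- if ("group" %in% names(profiles)) {
    p + geom_line(aes(colour = .data$group))
  } else {
    p + geom_line()
  }
  p + facet_wrap(~side, scales = "free_x") +
    labs(x = "oriented offset (bp)", y = "fraction of genes covered")
}

#' @importFrom rlang .data
NULL
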