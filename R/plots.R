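# ggplot2 views of the three result types: motif-class tallies, locus
# repeat-count variability, and PIC distributions.

#' @importFrom ggplot2 ggplot aes geom_col geom_point labs facet_wrap
#'   theme_minimal scale_fill_brewer position_stack
NULL

#' Plot SSR counts by canonical motif class
#'
#' @param object An `ssr_motif_summary` from [summarize_motifs()].
#' @param ... Unused.
#' @return A ggplot: counts per motif class, faceted by unit length.
#' @export
autoplot.ssr_motif_summary <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$motif_class, -.data$n),
                     y = .data$n)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~unit_length, scales = "free_x",
               labeller = ggplot2::labeller(
                 unit_length = function(u) paste0(u, "-mer"))) +
    labs(x = "motif class", y = "SSR runs") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot repeat-count variability of aggregated loci
#'
#' @param records Locus records from [aggregate_loci()].
#' @return A ggplot of observations vs distinct repeat counts per locus,
#'   colored by the polymorphic flag.
#' @export
plot_locus_variability <- function(records) {
  ggplot(records, aes(x = .data$n_obs, y = .data$n_distinct_repeats,
                      colour = .data$polymorphic)) +
    geom_point(alpha = 0.7, position = ggplot2::position_jitter(0.15, 0.15)) +
    labs(x = "observations at locus", y = "distinct repeat counts",
         colour = "polymorphic") +
    theme_minimal()
}

#' @export
autoplot.ssr_locus_records <- function(object, ...) plot_locus_variability(object)

#' Plot the PIC band breakdown by motif class
#'
#' Stacked percentage bars of loci falling in the PIC bands `[0,0.25]`
#' (weakly informative), `(0.25,0.5]` (reasonably informative), and
#' `(0.5,1)` (highly informative) within each motif class.
#'
#' @param stats Per-locus statistics with a `motif_class` column
#'   (see [marker_stats()]).
#' @return A ggplot.
#' @export
plot_pic_breakdown <- function(stats) {
  ggplot(pic_category_breakdown(stats),
         aes(x = .data$motif_class, y = .data$pct, fill = .data$pic_band)) +
    geom_col(position = position_stack()) +
    scale_fill_brewer(palette = "Blues", direction = -1) +
    labs(x = "motif class", y = "% of loci", fill = "PIC") +
    theme_minimal()
}

#' @export
autoplot.ssr_marker_stats <- function(object, ...) {
  if ("motif_class" %in% names(object) && any(!is.na(object$motif_class))) {
    return(plot_pic_breakdown(object))
  }
  ggplot(object, aes(x = .data$pic)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "steelblue") +
    labs(x = "PIC", y = "loci") +
    theme_minimal()
}
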