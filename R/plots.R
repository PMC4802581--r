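# ggplot2 displays for the result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a congruence table
#'
#' With branch durations attached the classic diagnostic is drawn: support
#' fraction (or count) against branch duration, one point per bipartition.
#' Without durations, a ranked bar chart of support fractions.
#'
#' @param object A `tbl_congruence`.
#' @param response `"fraction"` or `"n_support"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tbl_congruence
#' @export
autoplot.tbl_congruence <- function(object, response = c("fraction", "n_support"),
                                    ...) {
  response <- match.arg(response)
  ylab <- if (response == "fraction") "support fraction" else "supporting gene trees"
  if ("duration" %in% names(object)) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$duration, y = .data[[response]])) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4, colour = "grey40") +
      ggplot2::labs(x = "branch duration", y = ylab) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = stats::reorder(.data$bipartition_id,
                                                    .data[[response]]),
                                 y = .data[[response]])) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = "bipartition", y = ylab) +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot congrue_fit
#' @export
autoplot.congrue_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data[[object$x_name]],
                               y = .data[[object$y_name]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("adj. R² = %.3f, p = %.3g",
                         object$adj_r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Frequency distributions of per-locus statistics
#'
#' Faceted histograms of the per-locus metrics (taxa, length, variable and
#' informative sites, percent variation and missing data) — the standard
#' at-a-glance assessment of a phylogenomic dataset.
#'
#' @param profiles A [profile_loci()] tibble.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_locus_profiles <- function(profiles, bins = 30) {
  metrics <- c("n_taxa", "length", "n_pic", "pct_variation", "pct_missing")
  long <- tidyr::pivot_longer(profiles[, metrics], dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "loci") +
    ggplot2::theme_minimal()
}
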