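# ggplot2 views of the analysis objects. These return plots; styling is
# left to the caller.

#' @describeIn correlate_features Heatmap of Spearman coefficients,
#'   feature by tournament type, faceted by target.
#' @param object An `ipd_correlations` tibble.
#' @param ... Unused.
#' @method autoplot ipd_correlations
#' @export
autoplot.ipd_correlations <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tournament_type, y = .data$feature,
                               fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  name = "Spearman") +
    ggplot2::facet_wrap(ggplot2::vars(.data$target)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @describeIn fit_rank_regression Dot-and-whisker plot of the fitted
#'   coefficients (approximate 95% intervals), one panel per tournament
#'   type.
#' @param object An `ipd_rank_regression` object.
#' @method autoplot ipd_rank_regression
#' @export
autoplot.ipd_rank_regression <- function(object, ...) {
  coefs <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(coefs,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tournament_type)) +
    ggplot2::labs(x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn winner_profiles Histograms of the winner features, one
#'   row per tournament type.
#' @param object An `ipd_winner_profiles` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @method autoplot ipd_winner_profiles
#' @export
autoplot.ipd_winner_profiles <- function(object, bins = 25, ...) {
  ggplot2::ggplot(dplyr::filter(object$winners, !is.na(.data$value)),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "#4477aa",
                            colour = "white") +
    ggplot2::facet_grid(ggplot2::vars(.data$tournament_type),
                        ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::labs(x = NULL, y = "tournaments won") +
    ggplot2::theme_minimal()
}

#' Normalized-rank distributions of selected strategies
#'
#' Histograms of the normalized rank per tournament type, one row per
#' strategy — the standard view of how consistently a strategy places
#' across the tournaments it entered.
#'
#' @param features A feature table.
#' @param strategies Character vector of strategy names to show
#'   (default: all).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_rank_distributions <- function(features, strategies = NULL, bins = 20) {
  stopifnot(is.data.frame(features),
            all(c("name", "normalized_rank", "tournament_type") %in%
                  names(features)))
  if (!is.null(strategies)) {
    features <- dplyr::filter(features, .data$name %in% strategies)
  }
  ggplot2::ggplot(features, ggplot2::aes(x = .data$normalized_rank)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "#4477aa",
                            colour = "white") +
    ggplot2::facet_grid(ggplot2::vars(.data$name),
                        ggplot2::vars(.data$tournament_type)) +
    ggplot2::labs(x = "normalized rank r (0 = winner)", y = "tournaments") +
    ggplot2::theme_minimal()
}
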