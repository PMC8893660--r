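#' Plot a prevalence-versus-threshold curve
#'
#' @param curve Output of [prevalence_vs_threshold()].
#' @return A ggplot object.
#' @export
plot_prevalence_curve <- function(curve) {
  ggplot(curve, aes(x = .data$threshold, y = .data$proportion)) +
    geom_line(colour = "steelblue") +
    geom_point() +
    labs(x = "minimum rescue-junction read depth",
         y = "proportion of genes with a rescue form") +
    ylim(0, NA) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sr_prevalence <- function(object, ...) {
  plot_prevalence_curve(object)
}

#' Plot the 3n / non-3n frame spectrum of a junction catalogue
#'
#' Bars show the frame-class split of non-canonical junctions against the
#' two-thirds noisy-splicing null (dashed line).
#'
#' @param catalog Classified junction catalogue.
#' @return A ggplot object.
#' @export
plot_frame_spectrum <- function(catalog) {
  d <- catalog |>
    dplyr::filter(!.data$canonical, !is.na(.data$frame_class)) |>
    count(.data$frame_class) |>
    mutate(prop = .data$n / sum(.data$n))
  ggplot(d, aes(x = .data$frame_class, y = .data$prop)) +
    geom_col(fill = "grey40") +
    geom_hline(yintercept = 2 / 3, linetype = "dashed",
               colour = "firebrick") +
    labs(x = NULL, y = "fraction of non-canonical junctions") +
    theme_minimal()
}

#' Plot corrected diversity by region class and substitution class
#'
#' @param diversity Tibble with `region_class`, `substitution_class`,
#'   `pi_corrected` (e.g. [diversity_by_class()] results bound over
#'   regions).
#' @return A ggplot object.
#' @export
plot_region_diversity <- function(diversity) {
  ggplot(diversity, aes(x = .data$region_class, y = .data$pi_corrected)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~substitution_class, scales = "free_y") +
    labs(x = "region class", y = "content-corrected π") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
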