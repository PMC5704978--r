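# ggplot2 displays for the main result types.

#' Plot an agreement cross-classification as a tile heatmap
#'
#' @param object A `zr_agreement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zr_agreement <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tile_reference,
                                   y = .data$tile_analog, fill = .data$n)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_reverse(breaks = seq_len(object$k)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$k), position = "top") +
    ggplot2::labs(x = "reference tile", y = "derived tile",
                  title = sprintf("Tile agreement (kappa = %.2f, exact = %.0f%%)",
                                  object$weighted_kappa,
                                  100 * object$exact_agreement)) +
    ggplot2::theme_minimal()
}

#' Plot BLUP shrinkage of county predictions
#'
#' Segments from each county's raw mean to its BLUP, against effective ZIP
#' count: small counties are pulled hardest toward the grand mean.
#'
#' @param object A `zr_variance_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zr_variance_decomposition <- function(object, ...) {
  df <- object$blups
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_eff)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$n_eff,
                                       y = .data$county_mean, yend = .data$blup),
                          color = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$county_mean), size = 1) +
    ggplot2::geom_hline(yintercept = object$grand_mean, linetype = 2) +
    ggplot2::labs(x = "effective ZIPs per county", y = "county score",
                  title = sprintf("BLUP shrinkage (ICC = %.2f)", object$icc)) +
    ggplot2::theme_minimal()
}

#' Plot measure screening decisions
#'
#' Correlation of each candidate measure with its assigned subdomain
#' reference, coloured by decision, with the retention threshold marked.
#'
#' @param screening A `zr_screening` report.
#' @param r_min Retention threshold to mark (default 0.20).
#' @return A ggplot.
#' @export
plot_screening <- function(screening, r_min = 0.20) {
  df <- tidy(screening) |>
    dplyr::mutate(measure = stats::reorder(.data$measure, .data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$measure,
                                   color = .data$decision)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = r_min, linetype = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$subdomain),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Pearson r with assigned subdomain reference",
                  y = NULL, color = "decision") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' Plot derived against reference county domain scores
#'
#' @param analog Tibble of derived county scores (`county_id`,
#'   `health_factors`, `health_outcomes`).
#' @param reference County reference table with the same columns.
#' @return A ggplot with one panel per domain.
#' @export
plot_domain_scatter <- function(analog, reference) {
  doms <- c("health_factors", "health_outcomes")
  df <- dplyr::inner_join(
    tidyr::pivot_longer(analog[c("county_id", doms)], -"county_id",
                        names_to = "domain", values_to = "analog"),
    tidyr::pivot_longer(reference[c("county_id", doms)], -"county_id",
                        names_to = "domain", values_to = "reference"),
    by = c("county_id", "domain"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$analog)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$domain), scales = "free") +
    ggplot2::labs(x = "reference score", y = "derived analog score") +
    ggplot2::theme_minimal()
}
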