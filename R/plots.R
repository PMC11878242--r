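#' Plot yearly reporting trends
#'
#' Line plot of all reports and SMQ-matched reports per year, the usual way
#' reporting trends are displayed for a drug class.
#'
#' @param trend A [yearly_trend()] tibble.
#' @return A ggplot object.
#' @export
plot_yearly_trend <- function(trend) {
  long <- tidyr::pivot_longer(tibble::as_tibble(trend),
                              c("n_total", "n_smq"),
                              names_to = "series", values_to = "n")
  long$series <- factor(long$series, c("n_total", "n_smq"),
                        c("all reports", "SMQ-matched"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$n,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "year", y = "reports", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot yearly_trend
#' @export
autoplot.yearly_trend <- function(object, ...) plot_yearly_trend(object)

#' Plot serious-outcome rates per drug
#'
#' @param rates A [serious_rate()] tibble with a `drug` column.
#' @return A ggplot object.
#' @export
plot_serious_rates <- function(rates) {
  stopifnot("drug" %in% names(rates))
  d <- dplyr::mutate(rates,
                     drug = stats::reorder(.data$drug, -.data$percent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$drug, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_serious, .data$n_total)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "serious outcomes (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Forest-style plot of reporting odds ratios
#'
#' Point estimates with 95% intervals on a log scale, positives highlighted;
#' one row per exposure-event combination of a [signal_table()].
#'
#' @param signals A `signal_table` tibble.
#' @return A ggplot object.
#' @export
plot_signal_intervals <- function(signals) {
  d <- dplyr::filter(tibble::as_tibble(signals), !is.na(.data$ror))
  d <- dplyr::mutate(d, label = paste(.data$exposure, .data$event,
                                      sep = " / "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ror, y = .data$label,
                                  colour = .data$positive)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo,
                                         xmax = .data$ror_hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL,
                  colour = "positive signal") +
    ggplot2::theme_minimal()
}

#' @method autoplot signal_table
#' @export
autoplot.signal_table <- function(object, ...) plot_signal_intervals(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
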