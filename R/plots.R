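# ggplot2 views of the main result types.

#' Plot the round-wise relative-binding enrichment curve
#'
#' @param curve Tibble from [relative_binding()].
#' @return A ggplot object.
#' @export
plot_enrichment_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$round,
                                      y = .data$relative_binding)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = curve$round) +
    ggplot2::labs(x = "Selection round",
                  y = "Relative binding (round 0 = 1)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of binding parameters against expression ratios
#'
#' One panel per parameter, expression ratio on a log axis — the layout of
#' the usual motif-count-versus-expression mining figures.
#'
#' @param records Integration tibble from [build_integration_table()].
#' @param parameters Record columns to plot.
#' @return A ggplot object.
#' @export
plot_motif_expression <- function(records,
                                  parameters = c("n_GGCTAA", "n_GGCTGA",
                                                 "n_GGCTAG", "n_total")) {
  parameters <- intersect(parameters, names(records))
  long <- tidyr::pivot_longer(
    dplyr::select(records, "gene_id", "ratio",
                  dplyr::all_of(parameters)),
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "Parameter value", y = "Expression ratio") +
    ggplot2::theme_minimal()
}

#' Plot sensorgrams with an optional fitted overlay
#'
#' @param data Sensorgram tibble (`conc`, `phase`, `time`, `response`).
#' @param fit Optional `bli_fit`; when given, fitted curves are overlaid.
#' @return A ggplot object.
#' @export
plot_sensorgrams <- function(data, fit = NULL) {
  t_assoc <- if (is.null(fit)) max(data$time[data$phase == "association"])
  else fit$t_assoc
  data <- dplyr::mutate(data, t_abs = ifelse(.data$phase == "association",
                                             .data$time,
                                             .data$time + t_assoc))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$t_abs,
                                          y = .data$response,
                                          colour = factor(.data$conc * 1e9))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  colour = "Analyte (nM)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    fd <- dplyr::mutate(fit$data, fitted = fit$fitted,
                        t_abs = ifelse(.data$phase == "association",
                                       .data$time, .data$time + t_assoc))
    p <- p + ggplot2::geom_line(
      data = fd, ggplot2::aes(y = .data$fitted), linewidth = 0.6)
  }
  p
}

#' @rdname plot_sensorgrams
#' @param object A `bli_fit`.
#' @param ... Ignored.
#' @method autoplot bli_fit
#' @export
autoplot.bli_fit <- function(object, ...) {
  plot_sensorgrams(object$data, fit = object)
}
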