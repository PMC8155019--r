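#' Plot a correlation set
#'
#' Normalized auto- and cross-correlation curves with SEM ribbons, one
#' facet per signal pair.
#'
#' @param object A [correlate_traces()] result.
#' @param model Optional [build_model()] specification whose predicted
#'   curves are overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_set <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sem,
                                      ymax = .data$value + .data$sem),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = "lag (min)",
                  y = expression(G(tau) / bar(G)(0))) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    pred <- model_correlations(model, max_lag = max(abs(object$lag)),
                               dt = attr(object, "dt") %||% 1)
    p <- p + ggplot2::geom_line(data = pred, colour = "black",
                                linetype = "dashed")
  }
  p
}

#' Plot a fitted model against its data
#'
#' @param object A [fit_mle()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burst_fit <- function(object, ...) {
  autoplot(object$data$corr_set,
           model = build_model(object$variant, object$params))
}

#' Plot a simulated ChIP occupancy profile
#'
#' @param object A [simulate_chip()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chip_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$bin), .data$occupancy,
                               fill = .data$form)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "gene position bin (promoter → 3')",
                  y = "mean RNAP2 occupancy") +
    ggplot2::theme_minimal()
}

#' Plot intensity traces
#'
#' @param traces A `trace_set` tibble.
#' @param cells Optional subset of cell ids.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, cells = NULL) {
  d <- if (is.null(cells)) traces else
    traces[traces$cell_id %in% cells, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$intensity,
                                  colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::scale_colour_manual(values = c(ctd = "firebrick",
                                            ser5ph = "forestgreen",
                                            mrna = "royalblue")) +
    ggplot2::labs(x = "time (min)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot a perturbation response
#'
#' @param response A [perturbation_response()] tibble.
#' @param t_drug Optional drug time to mark.
#' @return A ggplot object.
#' @export
plot_perturbation <- function(response, t_drug = NULL) {
  p <- ggplot2::ggplot(response,
                       ggplot2::aes(.data$time, .data$mean,
                                    colour = .data$channel,
                                    fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "mean normalized intensity") +
    ggplot2::theme_minimal()
  if (!is.null(t_drug))
    p <- p + ggplot2::geom_vline(xintercept = t_drug, linetype = "dashed")
  p
}
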