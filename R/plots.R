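#' Raster plot of spike events
#'
#' @param object A [spike_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_ms, y = .data$source)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "source id") +
    ggplot2::theme_minimal()
}

#' Membrane and threshold traces for recorded neurons
#'
#' Shows the membrane potential together with the effective firing
#' threshold (base + adaptive component), one facet per neuron.
#'
#' @param object A `state_trace` from [simulate_liquid()].
#' @param neurons Neuron ids to show (default: first recorded neuron).
#' @param V_th_base Base threshold used to draw the effective threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.state_trace <- function(object, neurons = NULL, V_th_base = 15,
                                 ...) {
  df <- tidy(object)
  neurons <- neurons %||% object$neuron_ids[1]
  df <- dplyr::filter(df, .data$neuron %in% neurons)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$V, colour = "membrane")) +
    ggplot2::geom_line(ggplot2::aes(y = V_th_base + .data$theta_sfa,
                                    colour = "threshold")) +
    ggplot2::facet_wrap(~neuron, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(membrane = "black",
                                            threshold = "red")) +
    ggplot2::labs(x = "time (ms)", y = "mV", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Balance sweep diagnostics
#'
#' Mean net conductance (with its across-time standard deviation) and
#' spikes per neuron as a function of the input-inhibitory weight factor.
#'
#' @param object An `elsm_balance` tibble from [sweep_inhib_factor()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elsm_balance <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("factor", "mean_net_current", "sd_net_current",
                          "spikes_per_neuron")],
    -"factor", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "input-inhibitory weight factor", y = NULL) +
    ggplot2::theme_minimal()
}
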