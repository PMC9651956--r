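#' Sweep the input-inhibitory weight factor
#'
#' Explores how the relative width of the input-to-inhibitory weight
#' distribution (`U[0, factor * 0.4]` against the fixed excitatory
#' `U[0, 0.4]`) shifts the network's excitatory/inhibitory balance. For
#' each factor and each of `n_seeds` liquid initializations, all probe
#' inputs are simulated and the per-neuron net conductance statistics and
#' spike counts aggregated. Only the input-inhibitory weight magnitudes
#' differ between factors: topology, delays and every other weight are
#' identical at matched seeds.
#'
#' @param spec A [liquid_spec()] (its `inhib_factor` is overridden by the
#'   sweep).
#' @param probe_inputs List of [spike_raster()] probe samples sharing one
#'   channel count.
#' @param factors Factor grid (default
#'   `c(0.5, 0.75, 1, 1.5, 2, 2.5, 3)`; 0.5 is the classic baseline).
#' @param n_seeds Independent liquid initializations per factor (default 5).
#' @param config A [sim_config()] for the probe simulations.
#' @param seeds Optional explicit seed vector (length `n_seeds`).
#' @return An `elsm_balance` tibble: one row per factor with
#'   `mean_net_current`, `sd_net_current`, `spikes_per_neuron`,
#'   `exc_spikes_per_neuron` (all seed- and probe-averaged) and `n_seeds`.
#' @export
sweep_inhib_factor <- function(spec, probe_inputs,
                               factors = c(0.5, 0.75, 1, 1.5, 2, 2.5, 3),
                               n_seeds = 5, config = sim_config(),
                               seeds = NULL) {
  stopifnot(length(factors) >= 1, length(probe_inputs) >= 1)
  n_ch <- unique(vapply(probe_inputs, n_sources, integer(1)))
  if (length(n_ch) != 1) abort("Probe inputs must share one channel count.")
  seeds <- seeds %||% seq_len(n_seeds)
  base <- lapply(seeds, function(s) build_liquid(spec, n_ch, seed = s))
  rows <- purrr::map_dfr(factors, function(f) {
    per_seed <- purrr::map_dfr(seq_along(seeds), function(i) {
      liq <- set_inhib_factor(base[[i]], f)
      per_probe <- purrr::map_dfr(probe_inputs, function(inp) {
        sim <- simulate_liquid(liq, inp, config)
        st <- net_current_stats(sim, neurons = "exc")
        tibble(
          mean_net = st$mean_net_current,
          sd_net = st$sd_net_current,
          spn = spikes_per_neuron(sim),
          exc_spn = sum(sim$spike_counts[sim$is_excitatory]) /
            sum(sim$is_excitatory)
        )
      })
      dplyr::summarise(per_probe, dplyr::across(dplyr::everything(), mean))
    })
    tibble(
      factor = f,
      mean_net_current = mean(per_seed$mean_net),
      sd_net_current = mean(per_seed$sd_net),
      spikes_per_neuron = mean(per_seed$spn),
      exc_spikes_per_neuron = mean(per_seed$exc_spn),
      n_seeds = length(seeds)
    )
  })
  structure(rows, class = c("elsm_balance", class(rows)))
}

#' Select the balanced factor
#'
#' Balance holds where the time-averaged net conductance approaches zero;
#' the selected factor minimizes `|mean_net_current|`, with ties broken
#' toward the smaller factor.
#'
#' @param reports An `elsm_balance` tibble (or any data frame with
#'   `factor` and `mean_net_current` columns).
#' @return The selected factor (a single number).
#' @examples
#' r <- data.frame(factor = c(0.5, 1, 2, 3),
#'                 mean_net_current = c(0.15, 0.05, -0.01, -0.08))
#' select_balanced_factor(r) # 2
#' @export
select_balanced_factor <- function(reports) {
  if (nrow(reports) < 1) abort("At least one balance report is required.")
  ord <- order(abs(reports$mean_net_current), reports$factor)
  reports$factor[ord[1]]
}
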