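# Shared fixture builders and independent oracles.

# A small default liquid for simulator tests.
tiny_liquid <- function(n = 60, channels = 10, seed = 1, ...) {
  build_liquid(
    liquid_spec(n_neurons = n, input_in_degree = min(7L, channels), ...),
    n_channels = channels, seed = seed
  )
}

# Assemble an elsm_liquid by hand from explicit neuron/synapse tables,
# bypassing the random builder (for event-by-event oracles).
hand_liquid <- function(neurons, synapses, n_channels,
                        spec = liquid_spec(n_neurons = nrow(neurons))) {
  neurons$id <- seq_len(nrow(neurons))
  if (is.null(neurons$x)) neurons$x <- seq_len(nrow(neurons)) - 1
  if (is.null(neurons$y)) neurons$y <- 0
  if (is.null(neurons$z)) neurons$z <- 0
  if (is.null(neurons$tau_m)) neurons$tau_m <- 30
  if (is.null(neurons$tau_sfa)) neurons$tau_sfa <- NA_real_
  structure(
    list(neurons = tibble::as_tibble(neurons),
         synapses = tibble::as_tibble(synapses),
         n_channels = as.integer(n_channels), spec = spec, seed = 0L),
    class = "elsm_liquid"
  )
}

# Independent step-forward reference: explicit state machine, one frame at
# a time, written without reusing any package code.
sf_reference <- function(signal, threshold, baseline_init = "first-sample") {
  baseline <- if (identical(baseline_init, "zero")) 0 else signal[[1]]
  events <- integer(0)
  for (value in signal) {
    if (value > baseline + threshold) {
      events <- c(events, 1L)
      baseline <- baseline + threshold
    } else if (value < baseline - threshold) {
      events <- c(events, -1L)
      baseline <- baseline - threshold
    } else {
      events <- c(events, 0L)
    }
  }
  list(events = events, baseline = baseline)
}

# Poisson-ish regular input drive: every channel fires every `period` ms.
regular_input <- function(channels, duration, period = 10) {
  times <- seq(period, duration - 1, by = period)
  spike_raster(
    data.frame(source = rep(seq_len(channels), each = length(times)),
               t_ms = rep(times, channels)),
    n_sources = channels, duration_ms = duration
  )
}
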