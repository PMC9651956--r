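#' Simulation configuration
#'
#' @param dt Clock step in ms (default 1). Synaptic delays are rounded to
#'   the nearest step (minimum one step), so at `dt = 1` the 1.5 ms EE
#'   delay becomes 2 steps and the 0.8 ms delays one step; configure
#'   `dt <= 0.1` for exact delays.
#' @param duration_ms Simulated time; defaults to the input raster's
#'   duration. Rounded to a whole number of steps.
#' @param record Which neurons get full state traces (`V`, `g_e`, `g_i`,
#'   `theta_sfa` at every step): `"none"`, `"exc"` (excitatory only) or
#'   `"all"`. Net-current accumulators are always kept; full traces are
#'   only needed for plotting and diagnostics.
#' @param seed Seed for the initial membrane potentials.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 1, duration_ms = NULL,
                       record = c("none", "exc", "all"), seed = 1L) {
  stopifnot(dt > 0)
  structure(
    list(dt = dt, duration_ms = duration_ms, record = match.arg(record),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

round_half_up <- function(x) floor(x + 0.5)

# Group recurrent synapses by (delay step, source population) into n x n
# delivery matrices M[post, pre] = weight.
delivery_matrices <- function(liquid, dt) {
  syn <- liquid$synapses[liquid$synapses$type %in% REC_TYPES, ]
  n <- nrow(liquid$neurons)
  if (nrow(syn) == 0) return(list())
  dsteps <- pmax(1, round_half_up(syn$delay_ms / dt))
  src_exc <- substr(syn$type, 1, 1) == "E"
  groups <- split(seq_len(nrow(syn)), list(d = dsteps, e = src_exc),
                  drop = TRUE)
  lapply(groups, function(idx) {
    list(
      d = pmax(1, round_half_up(syn$delay_ms[idx[1]] / dt)),
      exc_source = src_exc[idx[1]],
      M = Matrix::sparseMatrix(i = syn$post[idx], j = syn$pre[idx],
                               x = syn$weight[idx], dims = c(n, n))
    )
  })
}

#' Run a clock-driven network simulation
#'
#' Advances every liquid neuron on a fixed `dt` grid. Each input or liquid
#' spike at time t delivers its conductance kick to every postsynaptic
#' target at `t + delay`, binned onto the grid by rounding half-up. Within
#' a step: scheduled kicks are applied, the membrane is integrated by
#' exponential Euler from the start-of-step conductances (refractory
#' neurons stay clamped at the reset potential while their clock runs
#' down), conductances and adaptive thresholds decay exactly, and the
#' threshold test fires at the step end. Spikes arriving at a refractory
#' target still increment its conductances. The run is deterministic given
#' `(liquid, input, config)`.
#'
#' @param liquid An [build_liquid()] result.
#' @param input A [spike_raster()] over the liquid's input channels.
#' @param config A [sim_config()].
#' @param params A [neuron_params()] supplying the shared constants;
#'   per-neuron `tau_m` / `tau_sfa` come from the liquid, and the
#'   refractory period is 3 ms for excitatory, 2 ms for inhibitory neurons.
#' @return An `elsm_sim` object: `raster` (liquid spikes as a
#'   [spike_raster()]), `trace` (a `state_trace`, or `NULL`),
#'   `spike_counts` (per neuron), per-neuron net-current accumulators, and
#'   run metadata.
#' @examples
#' liq <- build_liquid(liquid_spec(n_neurons = 30), n_channels = 8, seed = 1)
#' inp <- spike_raster(data.frame(source = rep(1:8, 5),
#'                                t_ms = rep(seq(10, 50, 10), each = 8)),
#'                     n_sources = 8, duration_ms = 100)
#' sim <- simulate_liquid(liq, inp, sim_config(seed = 1))
#' sim$raster
#' @export
simulate_liquid <- function(liquid, input, config = sim_config(),
                            params = neuron_params()) {
  stopifnot(inherits(liquid, "elsm_liquid"), inherits(input, "spike_raster"))
  if (n_sources(input) != liquid$n_channels) {
    abort(sprintf(
      "Input raster has %d channels but the liquid expects %d.",
      n_sources(input), liquid$n_channels
    ))
  }
  dt <- config$dt
  duration <- config$duration_ms %||% raster_duration(input)
  K <- max(1L, as.integer(round_half_up(duration / dt)))
  n <- nrow(liquid$neurons)
  is_exc <- liquid$neurons$is_excitatory
  tau_m <- liquid$neurons$tau_m
  t_ref <- ifelse(is_exc, params$t_ref, params$t_ref_inh)

  # Adaptive-threshold decay factor per neuron; 1 (= no decay, and no
  # increments either) where adaptation is off or the neuron is inhibitory.
  tau_sfa <- liquid$neurons$tau_sfa
  has_sfa <- !is.na(tau_sfa)
  dec_theta <- ifelse(has_sfa, exp(-dt / tau_sfa), 1)
  dec_e <- exp(-dt / params$tau_ge)
  dec_i <- exp(-dt / params$tau_gi)

  # Input delivery: dense n x n_channels weight matrix (fan-in is small).
  in_syn <- liquid$synapses[startsWith(liquid$synapses$type, "input"), ]
  W_in <- matrix(0, n, liquid$n_channels)
  if (nrow(in_syn) > 0) {
    W_in[cbind(in_syn$post, in_syn$pre)] <- in_syn$weight
  }
  d_in <- max(1, round_half_up(unname(liquid$spec$delays_ms[["input"]]) / dt))
  # Map input events to their arrival step.
  arrival <- round_half_up(input$t_ms / dt) + d_in
  keep <- arrival >= 1 & arrival <= K
  input_by_step <- split(input$source[keep], arrival[keep])

  groups <- delivery_matrices(liquid, dt)
  L <- max(c(1L, d_in, vapply(groups, function(g) g$d, numeric(1)))) + 1L

  set.seed(config$seed)
  V <- runif(n, params$E_reset, params$V_th_base)
  ge <- gi <- theta <- numeric(n)
  refrac <- numeric(n)
  buf_e <- matrix(0, n, L)
  buf_i <- matrix(0, n, L)

  spike_src <- vector("list", K)
  spike_counts <- integer(n)
  sum_net <- sum_net2 <- numeric(n)

  rec_ids <- switch(config$record,
                    none = integer(), exc = which(is_exc), all = seq_len(n))
  tracing <- length(rec_ids) > 0
  if (tracing) {
    tr <- lapply(c("V", "g_e", "g_i", "theta_sfa"), function(nm) {
      matrix(0, K + 1L, length(rec_ids))
    })
    names(tr) <- c("V", "g_e", "g_i", "theta_sfa")
    tr$V[1L, ] <- V[rec_ids]
  }

  Vth_base <- params$V_th_base
  sfa_inc <- params$sfa_increment
  E_rest <- params$E_rest; E_reset <- params$E_reset
  E_exc <- params$E_exc; E_inh <- params$E_inh

  for (k in seq_len(K)) {
    slot <- (k - 1L) %% L + 1L
    # deliver recurrent kicks scheduled for this step
    ge <- ge + buf_e[, slot]
    gi <- gi + buf_i[, slot]
    buf_e[, slot] <- 0
    buf_i[, slot] <- 0
    # deliver input kicks arriving this step
    ch <- input_by_step[[as.character(k)]]
    if (!is.null(ch)) {
      ge <- ge + if (length(ch) == 1L) W_in[, ch] else
        rowSums(W_in[, ch, drop = FALSE])
    }
    refractory <- refrac > 0
    # exponential-Euler membrane update from start-of-step conductances
    B <- 1 + ge + gi
    v_inf <- (E_rest + ge * E_exc + gi * E_inh) / B
    V <- v_inf + (V - v_inf) * exp(-B * (dt / tau_m))
    if (any(refractory)) {
      V[refractory] <- E_reset
      refrac[refractory] <- pmax(0, refrac[refractory] - dt)
    }
    ge <- ge * dec_e
    gi <- gi * dec_i
    theta <- theta * dec_theta
    sp <- !refractory & V >= Vth_base + theta
    if (any(sp)) {
      idx <- which(sp)
      V[idx] <- E_reset
      refrac[idx] <- t_ref[idx]
      bump <- idx[has_sfa[idx]]
      theta[bump] <- theta[bump] + sfa_inc
      spike_src[[k]] <- idx
      spike_counts[idx] <- spike_counts[idx] + 1L
      spv <- numeric(n)
      spv[idx] <- 1
      for (g in groups) {
        s2 <- (k - 1L + g$d) %% L + 1L
        kick <- as.numeric(g$M %*% spv)
        if (g$exc_source) buf_e[, s2] <- buf_e[, s2] + kick
        else buf_i[, s2] <- buf_i[, s2] + kick
      }
    }
    net <- ge - gi
    sum_net <- sum_net + net
    sum_net2 <- sum_net2 + net * net
    if (tracing) {
      tr$V[k + 1L, ] <- V[rec_ids]
      tr$g_e[k + 1L, ] <- ge[rec_ids]
      tr$g_i[k + 1L, ] <- gi[rec_ids]
      tr$theta_sfa[k + 1L, ] <- theta[rec_ids]
    }
  }

  n_ev <- lengths(spike_src)
  raster <- spike_raster(
    tibble(source = as.integer(unlist(spike_src)),
           t_ms = rep(seq_len(K) * dt, n_ev)),
    n_sources = n, duration_ms = K * dt
  )
  trace <- NULL
  if (tracing) {
    trace <- structure(
      list(neuron_ids = rec_ids, t_ms = 0:K * dt,
           V = tr$V, g_e = tr$g_e, g_i = tr$g_i, theta_sfa = tr$theta_sfa),
      class = "state_trace"
    )
  }
  structure(
    list(
      raster = raster, trace = trace,
      spike_counts = spike_counts,
      net_mean = sum_net / K,
      net_sd = sqrt(pmax(sum_net2 / K - (sum_net / K)^2, 0)),
      is_excitatory = is_exc,
      dt = dt, duration_ms = K * dt, config = config
    ),
    class = "elsm_sim"
  )
}

#' @export
print.elsm_sim <- function(x, ...) {
  cat(sprintf(
    "<elsm_sim> %.0f ms at dt %g ms: %d spikes (%.2f per neuron)\n",
    x$duration_ms, x$dt, nrow(x$raster),
    spikes_per_neuron(x$raster, length(x$spike_counts))
  ))
  invisible(x)
}

#' Average spike count per liquid neuron
#'
#' Total liquid events divided by the number of liquid neurons — the
#' network sparseness statistic used to compare model variants.
#'
#' @param raster A liquid [spike_raster()] (or an `elsm_sim`).
#' @param n_liquid Number of liquid neurons; defaults to the raster's
#'   source count.
#' @return A single number.
#' @export
spikes_per_neuron <- function(raster, n_liquid = NULL) {
  if (inherits(raster, "elsm_sim")) {
    n_liquid <- n_liquid %||% length(raster$spike_counts)
    raster <- raster$raster
  }
  n_liquid <- n_liquid %||% n_sources(raster)
  nrow(raster) / n_liquid
}

#' Net synaptic current balance diagnostics
#'
#' The net drive onto a neuron is summarized on bare conductances,
#' `net(t) = g_e(t) - g_i(t)`, averaged over simulated time; excitatory/
#' inhibitory balance holds where the network-average time-mean approaches
#' zero. Works on an `elsm_sim` (which accumulates the sums online for all
#' neurons) or on a recorded `state_trace`. Set
#' `driving_force = TRUE` on a trace to use `g * (E - V)` currents
#' instead.
#'
#' @param x An `elsm_sim` or `state_trace`.
#' @param neurons Which population enters the network averages: `"exc"`
#'   (default — the population the readout sees) or `"all"`.
#' @param driving_force Use `g_e (E_exc - V) + g_i (E_inh - V)` rather than
#'   `g_e - g_i` (trace method only).
#' @param params Neuron constants for the driving-force variant.
#' @param ... Unused.
#' @return A list with `per_neuron` (tibble: `id`, `mean_net`, `sd_net`),
#'   `mean_net_current` and `sd_net_current` (network averages), and
#'   `spikes_per_neuron` when available.
#' @export
net_current_stats <- function(x, ...) UseMethod("net_current_stats")

#' @rdname net_current_stats
#' @export
net_current_stats.elsm_sim <- function(x, neurons = c("exc", "all"), ...) {
  neurons <- match.arg(neurons)
  sel <- if (neurons == "exc") x$is_excitatory else rep(TRUE, length(x$net_mean))
  per <- tibble(id = which(sel), mean_net = x$net_mean[sel],
                sd_net = x$net_sd[sel])
  list(
    per_neuron = per,
    mean_net_current = mean(per$mean_net),
    sd_net_current = mean(per$sd_net),
    spikes_per_neuron = spikes_per_neuron(x)
  )
}

#' @rdname net_current_stats
#' @export
net_current_stats.state_trace <- function(x, driving_force = FALSE,
                                          params = neuron_params(), ...) {
  if (is.null(x$g_e) || nrow(x$g_e) == 0) abort("No recorded states.")
  net <- if (driving_force) {
    x$g_e * (params$E_exc - x$V) + x$g_i * (params$E_inh - x$V)
  } else {
    x$g_e - x$g_i
  }
  m <- colMeans(net)
  s <- apply(net, 2, function(v) sqrt(mean((v - mean(v))^2)))
  per <- tibble(id = x$neuron_ids, mean_net = m, sd_net = s)
  list(per_neuron = per,
       mean_net_current = mean(m),
       sd_net_current = mean(s))
}

#' Tidy a recorded state trace
#'
#' @param x A `state_trace` from [simulate_liquid()].
#' @param ... Unused.
#' @return A long tibble: `neuron`, `t_ms`, `V`, `g_e`, `g_i`,
#'   `theta_sfa`.
#' @export
tidy.state_trace <- function(x, ...) {
  n_rec <- length(x$neuron_ids)
  tibble(
    neuron = rep(x$neuron_ids, each = length(x$t_ms)),
    t_ms = rep(x$t_ms, n_rec),
    V = as.vector(x$V),
    g_e = as.vector(x$g_e),
    g_i = as.vector(x$g_i),
    theta_sfa = as.vector(x$theta_sfa)
  )
}
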