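#' Conductance-based LIF neuron parameters
#'
#' The membrane obeys
#' `tau * dV/dt = (E_rest - V) + g_e * (E_exc - V) + g_i * (E_inh - V)`,
#' with dimensionless conductances that decay exponentially
#' (`tau_ge = 3` ms excitatory, `tau_gi = 10` ms inhibitory) and jump by the
#' synaptic weight on presynaptic spike arrival. A spike is emitted when V
#' reaches the effective threshold `V_th_base + theta_sfa`; V then resets to
#' `E_reset` and the neuron is refractory for `t_ref` ms (3 ms excitatory,
#' 2 ms inhibitory). With adaptation on, each spike raises the adaptive
#' threshold component `theta_sfa` by `sfa_increment` (1 mV), which decays
#' back to zero with time constant `tau_sfa`.
#'
#' The voltage scale is the classic shifted one: rest and reset at 13.5 mV,
#' threshold at 15 mV, inhibitory reversal at 0 mV (hyperpolarizing, well
#' below rest on this scale) and excitatory reversal at 30 mV
#' (depolarizing, above threshold).
#'
#' @param E_rest,E_reset,E_exc,E_inh,V_th_base Potentials in mV.
#' @param tau_m Membrane time constant, ms.
#' @param tau_ge,tau_gi Conductance decay time constants, ms.
#' @param t_ref Refractory period, ms (the excitatory value; networks use
#'   `t_ref_inh` for inhibitory neurons).
#' @param t_ref_inh Inhibitory refractory period, ms.
#' @param sfa_increment Adaptive-threshold jump per spike, mV.
#' @param tau_sfa Adaptive-threshold decay time constant, ms (`NA` = no
#'   adaptation).
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(E_rest = 13.5, E_reset = 13.5, E_exc = 30,
                          E_inh = 0, V_th_base = 15, tau_m = 30,
                          tau_ge = 3, tau_gi = 10, t_ref = 3,
                          t_ref_inh = 2, sfa_increment = 1,
                          tau_sfa = NA_real_) {
  stopifnot(tau_m > 0, tau_ge > 0, tau_gi > 0, t_ref > 0, t_ref_inh > 0,
            V_th_base > E_reset)
  structure(
    list(E_rest = E_rest, E_reset = E_reset, E_exc = E_exc, E_inh = E_inh,
         V_th_base = V_th_base, tau_m = tau_m, tau_ge = tau_ge,
         tau_gi = tau_gi, t_ref = t_ref, t_ref_inh = t_ref_inh,
         sfa_increment = sfa_increment, tau_sfa = tau_sfa),
    class = "neuron_params"
  )
}

#' Initialize a neuron's dynamical state
#'
#' The membrane potential starts uniform on `[13.5, 15)` mV (between reset
#' and threshold); conductances, the adaptive threshold component, and the
#' refractory clock start at zero (no spike history).
#'
#' @param params A [neuron_params()].
#' @param seed Optional seed.
#' @return A `neuron_state` list with `V`, `g_e`, `g_i`, `theta_sfa`,
#'   `refractory_remaining`.
#' @export
init_state <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(V = runif(1, params$E_reset, params$V_th_base),
         g_e = 0, g_i = 0, theta_sfa = 0, refractory_remaining = 0),
    class = "neuron_state"
  )
}

#' Effective firing threshold
#'
#' `V_th = V_th_base + theta_sfa`: the static base plus the decaying
#' spike-history-dependent component.
#'
#' @param state A `neuron_state`.
#' @param params A [neuron_params()].
#' @return Threshold in mV.
#' @export
effective_threshold <- function(state, params) {
  params$V_th_base + state$theta_sfa
}

#' Register a presynaptic spike
#'
#' Conductances jump instantaneously by the synaptic weight: excitatory
#' sources increment `g_e`, inhibitory sources `g_i`. Weights are
#' non-negative; the hyperpolarizing effect of inhibitory input comes from
#' its reversal potential, not a negative weight.
#'
#' @param state A `neuron_state`.
#' @param weight Synaptic weight (conductance increment, >= 0).
#' @param inhibitory_source Did the spike come from an inhibitory neuron?
#' @return Updated state.
#' @export
apply_presynaptic_spike <- function(state, weight,
                                    inhibitory_source = FALSE) {
  if (any(weight < 0)) abort("Synaptic weights must be >= 0.")
  if (inhibitory_source) {
    state$g_i <- state$g_i + sum(weight)
  } else {
    state$g_e <- state$g_e + sum(weight)
  }
  state
}

#' Advance a single neuron by one time step
#'
#' One clock tick of length `dt`: the membrane is integrated over `dt` by
#' exponential Euler holding the start-of-step conductances fixed,
#' conductances and the adaptive threshold then decay exactly
#' (`g <- g * exp(-dt / tau_g)`), and the threshold test runs at the end of
#' the step. During the refractory period the membrane is clamped at
#' `E_reset` (conductances still decay) and no spike can be emitted. A
#' spike resets V, starts the refractory clock, and (when adaptation is
#' configured) raises `theta_sfa` by `sfa_increment`.
#'
#' With `g_e = g_i = 0` the update is the exact solution of the leak ODE:
#' `V(t + dt) = E_rest + (V(t) - E_rest) * exp(-dt / tau_m)`.
#'
#' @param state A `neuron_state`.
#' @param params A [neuron_params()].
#' @param dt Step size, ms (> 0).
#' @return `list(state = <updated state>, spiked = <logical>)`.
#' @examples
#' p <- neuron_params()
#' s <- init_state(p, seed = 1)
#' s$V <- 14; s$g_e <- 0
#' step_neuron(s, p, dt = 30)$state$V # 13.5 + 0.5 * exp(-1)
#' @export
step_neuron <- function(state, params, dt = 1) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$V, state$g_e, state$g_i, state$theta_sfa,
                       state$refractory_remaining)))) {
    abort("Non-finite neuron state.")
  }
  refractory <- state$refractory_remaining > 0
  if (refractory) {
    state$V <- params$E_reset
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
  } else {
    # tau dV/dt = A - B V with A, B from start-of-step conductances
    A <- params$E_rest + state$g_e * params$E_exc + state$g_i * params$E_inh
    B <- 1 + state$g_e + state$g_i
    v_inf <- A / B
    state$V <- v_inf + (state$V - v_inf) * exp(-B * dt / params$tau_m)
  }
  state$g_e <- state$g_e * exp(-dt / params$tau_ge)
  state$g_i <- state$g_i * exp(-dt / params$tau_gi)
  if (!is.na(params$tau_sfa) && state$theta_sfa > 0) {
    state$theta_sfa <- state$theta_sfa * exp(-dt / params$tau_sfa)
  }
  spiked <- FALSE
  if (!refractory && state$V >= effective_threshold(state, params)) {
    spiked <- TRUE
    state$V <- params$E_reset
    state$refractory_remaining <- params$t_ref
    if (!is.na(params$tau_sfa)) {
      state$theta_sfa <- state$theta_sfa + params$sfa_increment
    }
  }
  list(state = state, spiked = spiked)
}
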