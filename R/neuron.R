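# Hodgkin-Huxley membrane dynamics.
#
# Membrane equation per cell: C_m dV/dt = sum(I_n) + I_syn + I_ext, with
# sum(I_n) = g_Na m^3 h (E_Na - V) + g_K n^4 (E_K - V) + g_L (E_L - V)
# (positive current depolarizes) and conductance-based synapses
# I_syn = g_exc (E_exc - V) + g_inh (E_inh - V).  Two kinetic sets are
# implemented: classic squid-axon HH (e-neuron surrogate) and Wang-Buzsaki
# fast-spiking (i-neuron surrogate; m instantaneous, phi = 5).
# Integration: classic 4th-order Runge-Kutta on the coupled (V, m, h, n)
# system -- the standard scheme for this model family at dt = 0.05 ms, where
# first-order schemes visibly distort near-rheobase firing rates.  Synaptic
# conductances decay exactly exponentially between delivery events and enter
# the RK stages with their within-step analytic decay.  Gating variables are
# clamped to [0,1] after each step (RK4 can overshoot by rounding).  Spikes
# are upward crossings of V_th with a 1-ms absolute refractory period.

# x/(1 - exp(-x/s)) with the removable singularity at x = 0 filled in
vtrap <- function(x, s) ifelse(abs(x / s) < 1e-7, s * (1 + x / (2 * s)), x / (1 - exp(-x / s)))

gating_rates <- function(V, kinetics) {
  if (kinetics == "hh") {
    list(
      am = 0.1 * vtrap(V + 40, 10), bm = 4 * exp(-(V + 65) / 18),
      ah = 0.07 * exp(-(V + 65) / 20), bh = 1 / (1 + exp(-(V + 35) / 10)),
      an = 0.01 * vtrap(V + 55, 10), bn = 0.125 * exp(-(V + 65) / 80),
      m_inst = FALSE
    )
  } else {  # Wang-Buzsaki
    list(
      am = 0.1 * vtrap(V + 35, 10), bm = 4 * exp(-(V + 60) / 18),
      ah = 0.07 * exp(-(V + 58) / 20), bh = 1 / (1 + exp(-(V + 28) / 10)),
      an = 0.01 * vtrap(V + 34, 10), bn = 0.125 * exp(-(V + 44) / 80),
      m_inst = TRUE
    )
  }
}

#' Construct a neuron state vector
#'
#' Gating variables start at their steady-state values for the initial
#' voltage; synaptic conductances start at zero.
#'
#' @param n number of cells.
#' @param params [neuron_params()] shared by the cells.
#' @param V initial membrane potential (mV), scalar or length-`n`.
#' @return A `glia_neuron_state` list of per-cell vectors (`V`, `m`, `h`,
#'   `n`, `g_exc`, `g_inh`, `ref_until`, `t`).
#' @export
neuron_state <- function(n, params, V = params$E_L) {
  V <- rep_len(V, n)
  r <- gating_rates(V, params$kinetics)
  structure(list(
    V = V,
    m = r$am / (r$am + r$bm),
    h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn),
    g_exc = numeric(n), g_inh = numeric(n),
    ref_until = rep(-Inf, n), t = 0
  ), class = "glia_neuron_state")
}

check_state_finite <- function(state) {
  bad <- which(!is.finite(state$V) | !is.finite(state$m) |
                 !is.finite(state$h) | !is.finite(state$n))
  if (length(bad))
    stop(sprintf("integration failure: non-finite state in cell %d at t = %g ms",
                 bad[1L], state$t), call. = FALSE)
  invisible(state)
}

#' Total ionic membrane current
#'
#' `sum(I_n) = g_Na m^3 h (E_Na - V) + g_K n^4 (E_K - V) + g_L (E_L - V)`
#' per cell, in uA/cm^2; positive values depolarize.
#'
#' @param state a `glia_neuron_state`.
#' @param params [neuron_params()].
#' @return numeric vector of currents.
#' @export
channel_currents <- function(state, params) {
  check_state_finite(state)
  params$g_Na * state$m^3 * state$h * (params$E_Na - state$V) +
    params$g_K * state$n^4 * (params$E_K - state$V) +
    params$g_L * (params$E_L - state$V)
}

#' Synaptic current
#'
#' `I_syn = g_exc (E_exc - V) + g_inh (E_inh - V)` per cell (uA/cm^2).
#'
#' @inheritParams channel_currents
#' @return numeric vector of currents.
#' @export
synaptic_current <- function(state, params) {
  stopifnot(all(state$g_exc >= 0), all(state$g_inh >= 0))
  state$g_exc * (params$E_exc - state$V) + state$g_inh * (params$E_inh - state$V)
}

#' Probabilistic spike delivery
#'
#' One Bernoulli trial per synapse record, success probability `p`, drawn
#' from the synapse's dedicated counter-based stream keyed by
#' `(seed, syn_id, event_index)`.  On success the synapse schedules a
#' conductance increment `w` on the postsynaptic cell at
#' `spike time + delay`; on failure it has no effect.
#'
#' @param syn one or more `glia_connectivity` rows (needs `syn_id`, `p`,
#'   `w`, `post`, `delay`).
#' @param seed master seed.
#' @param event_index per-synapse presynaptic event counter (0-based),
#'   recycled to `nrow(syn)`.
#' @param spike_time presynaptic spike time (ms).
#' @return data frame of scheduled increments (`post`, `w`, `at`, `class`)
#'   for the delivered subset; zero rows when nothing is released.
#' @export
deliver_spike <- function(syn, seed, event_index, spike_time = 0) {
  hit <- counter_bernoulli(seed, syn$syn_id, event_index, syn$p)
  data.frame(post = syn$post[hit], w = syn$w[hit],
             at = spike_time + syn$delay[hit],
             class = syn$class[hit], stringsAsFactors = FALSE)
}

# time derivatives of (V, m, h, n) given synaptic conductances at stage time
neuron_derivs <- function(V, m, h, n, gE, gI, I_ext, params) {
  r <- gating_rates(V, params$kinetics)
  if (r$m_inst) m <- r$am / (r$am + r$bm)
  I <- params$g_Na * m^3 * h * (params$E_Na - V) +
    params$g_K * n^4 * (params$E_K - V) +
    params$g_L * (params$E_L - V) +
    gE * (params$E_exc - V) + gI * (params$E_inh - V) + I_ext
  list(
    dV = I / params$C_m,
    dm = if (r$m_inst) 0 else r$am * (1 - m) - r$bm * m,
    dh = params$phi * (r$ah * (1 - h) - r$bh * h),
    dn = params$phi * (r$an * (1 - n) - r$bn * n)
  )
}

#' Advance neurons by one time step
#'
#' Classic RK4 on the coupled membrane/gating system; synaptic conductances
#' decay exactly exponentially (`g(t+d) = g(t) exp(-d/tau)`) and enter the
#' RK stages with their analytic within-step decay.  Emits a spike for every
#' cell whose voltage crosses `V_th` upward outside its 1-ms absolute
#' refractory period.
#'
#' @param state a `glia_neuron_state`.
#' @param I_ext external current (uA/cm^2), scalar or per-cell.
#' @param dt step (ms).
#' @param params [neuron_params()].
#' @param t_ref absolute refractory period (ms).
#' @return list with the advanced `state` and integer vector `spikes` of
#'   cell ids that fired during this step.
#' @export
step_neurons <- function(state, I_ext, dt, params, t_ref = 1) {
  stopifnot(dt > 0)
  check_state_finite(state)
  I_ext <- rep_len(I_ext, length(state$V))
  gE_h <- state$g_exc * exp(-dt / (2 * params$tau_exc))
  gI_h <- state$g_inh * exp(-dt / (2 * params$tau_inh))
  gE_f <- state$g_exc * exp(-dt / params$tau_exc)
  gI_f <- state$g_inh * exp(-dt / params$tau_inh)
  k1 <- neuron_derivs(state$V, state$m, state$h, state$n,
                      state$g_exc, state$g_inh, I_ext, params)
  k2 <- neuron_derivs(state$V + dt / 2 * k1$dV, state$m + dt / 2 * k1$dm,
                      state$h + dt / 2 * k1$dh, state$n + dt / 2 * k1$dn,
                      gE_h, gI_h, I_ext, params)
  k3 <- neuron_derivs(state$V + dt / 2 * k2$dV, state$m + dt / 2 * k2$dm,
                      state$h + dt / 2 * k2$dh, state$n + dt / 2 * k2$dn,
                      gE_h, gI_h, I_ext, params)
  k4 <- neuron_derivs(state$V + dt * k3$dV, state$m + dt * k3$dm,
                      state$h + dt * k3$dh, state$n + dt * k3$dn,
                      gE_f, gI_f, I_ext, params)
  V_new <- state$V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  if (any(abs(V_new) > 500))
    stop(sprintf("integration divergence (|V| > 500 mV) at t = %g ms; reduce dt",
                 state$t + dt), call. = FALSE)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  m_new <- clamp01(state$m + dt / 6 * (k1$dm + 2 * k2$dm + 2 * k3$dm + k4$dm))
  h_new <- clamp01(state$h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh))
  n_new <- clamp01(state$n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn))
  r_new <- gating_rates(V_new, params$kinetics)
  if (r_new$m_inst) m_new <- r_new$am / (r_new$am + r_new$bm)
  t_new <- state$t + dt
  crossing <- state$V < params$V_th & V_new >= params$V_th &
    t_new >= state$ref_until
  spikes <- which(crossing)
  state$ref_until[spikes] <- t_new + t_ref
  state$V <- V_new
  state$m <- m_new; state$h <- h_new; state$n <- n_new
  state$g_exc <- gE_f
  state$g_inh <- gI_f
  state$t <- t_new
  list(state = state, spikes = spikes)
}
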