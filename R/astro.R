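# Astrocyte Ca2+ dynamics and gliotransmission.
#
# Each astrocyte carries cytosolic Ca (uM), an IP3 pool (uM) and an IP3R
# inactivation gate q.  Ca follows a two-variable Li-Rinzel-type scheme
#   dCa/dt = J_chan + J_leak - J_pump + J_gj
# with IP3R channel release J_chan = c1 v1 m_inf^3 q^3 (c_ER - Ca),
# ER leak J_leak = c1 v2 (c_ER - Ca), SERCA uptake
# J_pump = v3 Ca^2/(Ca^2 + k3^2), c_ER = (c0 - Ca)/c1, and direct
# gap-junction exchange J_gj = sum_j g_gj (Ca_j - Ca_i) (antisymmetric, so
# coupling alone conserves total Ca).  IP3 relaxes exponentially to its
# baseline and jumps by a fixed gain for every presynaptic spike inside the
# astrocyte's territory; elevated IP3 pushes the oscillator into its active
# range, raising (time-averaged) Ca with domain activity.
# Ca is finally mapped onto the release probability of covered excitatory
# synapses through a Hill sigmoid p(Ca) = p0 + (p_max - p0) Ca^n/(Ca^n+K^n).

#' Construct an astrocyte state
#'
#' @param n number of astrocytes.
#' @param params [astro_params()].
#' @return A `glia_astro_state` list of per-cell vectors `Ca` (uM),
#'   `IP3` (uM) and gate `q` in `[0,1]`.
#' @export
astro_state <- function(n, params) {
  structure(list(Ca = rep(params$Ca0, n),
                 IP3 = rep(params$ip3_baseline, n),
                 q = rep(params$q0, n)),
            class = "glia_astro_state")
}

# Laplacian action of the gap-junction graph on a per-astrocyte quantity
gap_exchange <- function(x, gj) {
  out <- numeric(length(x))
  if (!is.null(gj) && nrow(gj)) {
    flux <- gj$g * (x[gj$b] - x[gj$a])
    s <- rowsum(c(flux, -flux), c(gj$a, gj$b))
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Net calcium flux per astrocyte
#'
#' Returns `dCa/dt` (uM/ms): IP3R channel release + ER leak - SERCA uptake +
#' gap-junction exchange.
#'
#' @param state a `glia_astro_state`.
#' @param params [astro_params()].
#' @param gj optional `glia_gapjunctions` edge table.
#' @return numeric vector, uM/ms.
#' @export
ca_fluxes <- function(state, params, gj = NULL) {
  if (any(state$Ca < 0)) stop("negative astrocyte Ca", call. = FALSE)
  Ca <- state$Ca
  c_ER <- (params$c0 - Ca) / params$c1
  m_inf <- (state$IP3 / (state$IP3 + params$d1)) * (Ca / (Ca + params$d5))
  J_chan <- params$c1 * params$v1 * m_inf^3 * state$q^3 * (c_ER - Ca)
  J_leak <- params$c1 * params$v2 * (c_ER - Ca)
  J_pump <- params$v3 * Ca^2 / (Ca^2 + params$k3^2)
  J_chan + J_leak - J_pump + gap_exchange(Ca, gj)
}

#' IP3 increment from covered presynaptic activity
#'
#' Every presynaptic spike inside an astrocyte's territory adds a fixed IP3
#' gain; between spikes IP3 decays exponentially toward its baseline (the
#' decay is applied by [step_astro()]).
#'
#' @param spike_counts integer vector, spikes per astrocyte domain in the
#'   update interval.
#' @param params [astro_params()].
#' @return numeric vector of IP3 increments (uM).
#' @export
ip3_drive <- function(spike_counts, params) {
  spike_counts * params$ip3_gain
}

#' Calcium-dependent release probability
#'
#' Hill sigmoid `p(Ca) = p0 + (p_max - p0) Ca^n_H / (Ca^n_H + K_Ca^n_H)`:
#' monotone non-decreasing, `p(0) = p0`, half-way at `Ca = K_Ca`, saturating
#' at `p_max`.  This maps astrocyte Ca onto the neurotransmitter release
#' probability of the synapses the astrocyte covers.
#'
#' @param Ca calcium concentration (uM, >= 0), vectorised.
#' @param params [astro_params()].
#' @return numeric vector of probabilities in `[p0, p_max]`.
#' @export
release_prob <- function(Ca, params) {
  stopifnot(all(Ca >= 0))
  params$p0 + (params$p_max - params$p0) *
    Ca^params$n_H / (Ca^params$n_H + params$K_Ca^params$n_H)
}

#' Apply astrocytic modulation to synaptic release probability
#'
#' Sets `p` of every covered synapse in the selected classes to
#' `release_prob(Ca)` of its covering astrocyte.  Uncovered synapses and
#' inhibitory (`ie`/`ii`) synapses are untouched; with `enabled = FALSE` the
#' table is returned unchanged.
#'
#' @param domains a `glia_domains` map.
#' @param state a `glia_astro_state`.
#' @param syn `glia_connectivity` table.
#' @param params [astro_params()].
#' @param classes which classes to modulate (subset of `c("ee","ei")`).
#' @param enabled logical switch.
#' @return the modified `glia_connectivity` table.
#' @export
apply_glia_modulation <- function(domains, state, syn, params,
                                  classes = c("ee", "ei"), enabled = TRUE) {
  if (!enabled) return(syn)
  idx <- which(!is.na(domains$syn_astro) & syn$class %in% classes)
  if (length(idx)) {
    a <- domains$syn_astro[idx]
    if (any(a > length(state$Ca)))
      stop("dangling astrocyte domain reference", call. = FALSE)
    syn$p[idx] <- release_prob(state$Ca[a], params)
  }
  syn
}

#' Advance astrocytes by one step
#'
#' IP3: exact exponential relaxation to baseline plus the spike-driven jump
#' from [ip3_drive()].  Gate q: exponential Euler on the Li-Rinzel
#' inactivation kinetics.  Ca: forward Euler on [ca_fluxes()].
#'
#' @param state a `glia_astro_state`.
#' @param params [astro_params()].
#' @param gj gap-junction edge table or `NULL`.
#' @param spike_counts per-domain presynaptic spike counts for this interval.
#' @param dt step (ms).
#' @return the advanced `glia_astro_state`.
#' @export
step_astro <- function(state, params, gj, spike_counts, dt) {
  state$IP3 <- params$ip3_baseline +
    (state$IP3 - params$ip3_baseline) * exp(-dt / params$tau_ip3) +
    ip3_drive(spike_counts, params)
  a_q <- params$a2 * params$d2 * (state$IP3 + params$d1) / (state$IP3 + params$d3)
  b_q <- params$a2 * state$Ca
  q_inf <- a_q / (a_q + b_q)
  state$q <- q_inf + (state$q - q_inf) * exp(-dt * (a_q + b_q))
  state$Ca <- pmax(state$Ca + dt * ca_fluxes(state, params, gj), 0)
  state
}
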