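# Synaptic modification rules.
#
# Two rules are available.  STDP: exponential kernel on the pre-post spike
# time difference, nearest-neighbour pairing, additive updates clipped to
# [w_min, w_max].  FREQ: linear-threshold rule on the presynaptic firing
# rate, applied at a fixed cadence.  During recall the rule is disabled and
# the weight matrix is returned untouched, bit for bit.

#' Define a plasticity rule
#'
#' @param kind `"STDP"`, `"FREQ"` or `"NONE"`.
#' @param A_plus,A_minus STDP potentiation/depression amplitudes
#'   (mS/cm^2, >= 0).
#' @param tau_plus,tau_minus STDP kernel time constants (ms).
#' @param theta_r FREQ rate threshold (Hz).
#' @param gain FREQ weight change per Hz above/below threshold, per update.
#' @param cadence FREQ update interval (ms).
#' @param w_min,w_max weight bounds (mS/cm^2).
#' @param classes which connection classes are plastic.
#' @param pair_window nearest-neighbour pairing window, in multiples of the
#'   kernel time constant.
#' @return A `glia_plasticity_rule` list with an `enabled` flag
#'   (`kind != "NONE"`).
#' @export
plasticity_rule <- function(kind = c("NONE", "STDP", "FREQ"),
                            A_plus = 5e-4, A_minus = 5.25e-4,
                            tau_plus = 20, tau_minus = 20,
                            theta_r = 10, gain = 1e-5, cadence = 100,
                            w_min = 0, w_max = 0.006,
                            classes = "ee", pair_window = 5) {
  kind <- match.arg(kind)
  stopifnot(A_plus >= 0, A_minus >= 0, tau_plus > 0, tau_minus > 0,
            w_min <= w_max, cadence > 0, pair_window > 0)
  structure(list(kind = kind, A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 theta_r = theta_r, gain = gain, cadence = cadence,
                 w_min = w_min, w_max = w_max, classes = classes,
                 pair_window = pair_window,
                 enabled = kind != "NONE"),
            class = "glia_plasticity_rule")
}

#' STDP weight change for one spike pair
#'
#' `dt_pre_post = t_post - t_pre`.  Post-after-pre (`dt > 0`) potentiates by
#' `A_plus * exp(-dt/tau_plus)`; pre-after-post (`dt < 0`) depresses by
#' `A_minus * exp(-|dt|/tau_minus)`; coincident spikes (`dt = 0`) leave the
#' weight unchanged.
#'
#' @param dt_pre_post spike time difference(s), ms; vectorised.
#' @param rule a [plasticity_rule()] of kind `"STDP"`.
#' @return numeric vector of weight increments.
#' @export
stdp_delta <- function(dt_pre_post, rule) {
  stopifnot(rule$kind == "STDP")
  ifelse(dt_pre_post > 0,
         rule$A_plus * exp(-dt_pre_post / rule$tau_plus),
         ifelse(dt_pre_post < 0,
                -rule$A_minus * exp(dt_pre_post / rule$tau_minus),
                0))
}

#' Frequency-dependent weight change
#'
#' `dw = gain * (rate - theta_r)` per update interval: potentiation above
#' the rate threshold, depression below it.
#'
#' @param presyn_rate trailing-window presynaptic firing rate (Hz).
#' @param rule a [plasticity_rule()] of kind `"FREQ"`.
#' @return numeric vector of weight increments.
#' @export
freq_delta <- function(presyn_rate, rule) {
  stopifnot(rule$kind == "FREQ")
  rule$gain * (presyn_rate - rule$theta_r)
}

#' Apply a plasticity rule to a connectivity table given a spike record
#'
#' Offline replay of the rule over a spike event list.  For STDP each spike
#' is paired with the nearest preceding spike of the opposite side
#' (nearest-neighbour pairing) when it falls within `pair_window` kernel
#' time constants; increments accumulate in event order and weights are
#' clipped to `[w_min, w_max]` after every update, exactly as the simulation
#' engine applies the rule online.  For FREQ, each synapse is updated once
#' per cadence interval from its presynaptic trailing rate.  A disabled rule
#' returns `syn` unchanged.
#'
#' @param syn `glia_connectivity` table.
#' @param events data frame of spikes with columns `cell`, `t` (ms).
#' @param rule a [plasticity_rule()].
#' @param T_total spike-record duration (ms), needed for FREQ cadence;
#'   defaults to `max(events$t)`.
#' @return the updated `glia_connectivity` table.
#' @export
apply_plasticity <- function(syn, events, rule, T_total = NULL) {
  if (!rule$enabled) return(syn)
  plastic <- which(syn$class %in% rule$classes)
  if (!length(plastic) || !nrow(events)) return(syn)
  events <- events[order(events$t, events$cell), , drop = FALSE]
  if (rule$kind == "STDP") {
    by_pre <- split(plastic, syn$pre[plastic])
    by_post <- split(plastic, syn$post[plastic])
    last_spike <- rep(-Inf, max(c(syn$pre, syn$post, events$cell)))
    # spikes sharing a timestamp see last_spike frozen at its pre-step values
    # (coincident pre/post pairs contribute nothing, the declared tie rule)
    for (t in unique(events$t)) {
      grp <- events$cell[events$t == t]
      for (cell in grp) {
        # as postsynaptic spike: potentiate inputs whose pre fired before t
        for (s in by_post[[as.character(cell)]]) {
          dtp <- t - last_spike[syn$pre[s]]
          if (is.finite(dtp) && dtp > 0 && dtp <= rule$pair_window * rule$tau_plus)
            syn$w[s] <- clip(syn$w[s] + stdp_delta(dtp, rule), rule)
        }
        # as presynaptic spike: depress outputs whose post fired before t
        for (s in by_pre[[as.character(cell)]]) {
          dtd <- last_spike[syn$post[s]] - t
          if (is.finite(dtd) && dtd < 0 && -dtd <= rule$pair_window * rule$tau_minus)
            syn$w[s] <- clip(syn$w[s] + stdp_delta(dtd, rule), rule)
        }
      }
      last_spike[grp] <- t
    }
  } else if (rule$kind == "FREQ") {
    if (is.null(T_total)) T_total <- max(events$t)
    breaks <- seq(0, T_total, by = rule$cadence)
    if (length(breaks) < 2) return(syn)
    for (b in seq_len(length(breaks) - 1L)) {
      win <- events$t > breaks[b] & events$t <= breaks[b + 1L]
      counts <- tabulate(events$cell[win], nbins = length(last_spike_bins(syn)))
      rate <- counts * 1000 / rule$cadence  # Hz
      dw <- freq_delta(rate[syn$pre[plastic]], rule)
      syn$w[plastic] <- clip(syn$w[plastic] + dw, rule)
    }
  }
  syn
}

clip <- function(w, rule) pmin(pmax(w, rule$w_min), rule$w_max)

last_spike_bins <- function(syn) seq_len(max(c(syn$pre, syn$post)))
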