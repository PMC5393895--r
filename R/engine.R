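# The simulation engine.
#
# Time loop over [0, T] at step dt:
#   deliver due synaptic conductance increments (ring buffer) ->
#   step neurons (per worker block) -> probabilistic delivery of new spikes ->
#   online plasticity -> astrocyte IP3/Ca update and release-probability
#   modulation (every astro_stride steps).
# Cells are partitioned across `workers` contiguous index blocks and stepped
# block by block, with spike events exchanged globally once per step (delays
# >= dt make this exact).  All stochastic release draws come from
# counter-based streams keyed by (seed, synapse id, presynaptic event index),
# and every remaining draw (placement, wiring, initial voltages) is made
# once, globally, before the loop -- so the trajectory is bit-identical for
# any worker count.  The loop state is a plain list, which doubles as the
# checkpoint: resuming a checkpoint replays exactly the arithmetic of an
# unbroken run.

prepare_sim <- function(network, config, connectivity = NULL) {
  syn <- if (is.null(connectivity)) network$synapses else {
    s <- connectivity
    if (is.null(s$syn_id)) s$syn_id <- seq_len(nrow(s))
    s
  }
  n_e <- config$n_e; n_i <- config$n_i; n <- n_e + n_i
  dt <- config$dt
  delay_steps <- if (nrow(syn)) pmax(1L, as.integer(round(syn$delay / dt))) else integer(0)
  n_slots <- max(2L, if (length(delay_steps)) max(delay_steps) + 1L else 2L)
  fpre <- factor(syn$pre, levels = seq_len(n))
  rule <- config$plasticity
  plastic <- which(syn$class %in% rule$classes)
  list(
    n_e = n_e, n_i = n_i, n = n, dt = dt, n_slots = n_slots,
    syn_pre = syn$pre, syn_post = syn$post, syn_id = syn$syn_id,
    syn_class = syn$class, syn_delay = syn$delay,
    delay_steps = delay_steps,
    syn_exc = syn$class %in% c("ee", "ei"),
    out_syn = split(seq_len(nrow(syn)), fpre),
    plastic_by_pre = split(plastic, factor(syn$pre[plastic], levels = seq_len(n))),
    plastic_by_post = split(plastic, factor(syn$post[plastic], levels = seq_len(n))),
    rule = rule,
    params_e = config$neuron_e, params_i = config$neuron_i,
    astro = config$astro,
    cell_astro = if (!is.null(network$domains)) network$domains$cell_astro else NULL,
    domains = network$domains,
    gj = network$gap_junctions,
    n_a = config$n_a,
    syn_w0 = syn$w, syn_p0 = syn$p
  )
}

init_sim_state <- function(prep, config) {
  # dedicated derived seed: the initial-voltage jitter is the same whether or
  # not the caller reused a prebuilt network
  set.seed((config$seed + 777L) %% .Machine$integer.max)
  V_e <- stats::runif(prep$n_e, config$V_init_range[1L], config$V_init_range[2L])
  V_i <- stats::runif(prep$n_i, config$V_init_range[1L], config$V_init_range[2L])
  list(
    step = 0L,
    state_e = neuron_state(prep$n_e, prep$params_e, V_e),
    state_i = neuron_state(prep$n_i, prep$params_i, V_i),
    astro = if (prep$n_a > 0) astro_state(prep$n_a, prep$astro) else NULL,
    bufE = matrix(0, prep$n_slots, prep$n),
    bufI = matrix(0, prep$n_slots, prep$n),
    w = prep$syn_w0, p = prep$syn_p0,
    spike_count = integer(prep$n),      # counter-based RNG event indices
    last_spike = rep(-Inf, prep$n),     # for nearest-neighbour STDP
    dom_spikes = if (prep$n_a > 0) integer(prep$n_a) else NULL,
    freq_counts = integer(prep$n)       # trailing spike counts for FREQ rule
  )
}

slice_state <- function(state, idx) {
  s <- state
  for (f in c("V", "m", "h", "n", "g_exc", "g_inh", "ref_until"))
    s[[f]] <- state[[f]][idx]
  s
}

# note: the population clock is advanced once per step by the caller, not
# here -- a block's slice steps its private copy of t only
merge_state <- function(state, sub, idx) {
  for (f in c("V", "m", "h", "n", "g_exc", "g_inh", "ref_until"))
    state[[f]][idx] <- sub[[f]]
  state
}

# contiguous index blocks: cell c -> block floor((c-1)*k/n)+1
worker_blocks <- function(n, k) {
  if (n == 0) return(list())
  split(seq_len(n), floor((seq_len(n) - 1) * k / n) + 1L)
}

run_loop <- function(S, prep, config, ep, n_steps, workers,
                     ca_every_steps = NULL) {
  dt <- prep$dt
  n_e <- prep$n_e; n <- prep$n
  seed <- config$seed
  rule <- prep$rule
  glia_on <- config$glia_enabled && prep$n_a > 0
  stride <- config$astro_stride
  if (is.null(ca_every_steps))
    ca_every_steps <- max(stride, as.integer(round(10 / dt)))
  blocks_e <- worker_blocks(n_e, workers)
  blocks_i <- worker_blocks(prep$n_i, workers)
  I_bg_e <- rep_len(config$I_bg_e, n_e)
  I_bg_i <- rep_len(config$I_bg_i, prep$n_i)
  ep_mask <- if (!is.null(ep)) which(rep_len(ep$mask, n_e)) else integer(0)
  freq_steps <- max(1L, as.integer(round(rule$cadence / dt)))

  sp_cells <- vector("list", n_steps)
  sp_times <- vector("list", n_steps)
  ca_rec <- list(); ca_t <- numeric(0)

  for (k in seq_len(n_steps)) {
    g <- S$step + 1L                      # global step number (1-based)
    t_prev <- S$state_e$t
    slot <- ((g - 1L) %% prep$n_slots) + 1L

    # 1. deliver due conductance increments
    S$state_e$g_exc <- S$state_e$g_exc + S$bufE[slot, seq_len(n_e)]
    S$state_e$g_inh <- S$state_e$g_inh + S$bufI[slot, seq_len(n_e)]
    if (prep$n_i > 0) {
      ii <- (n_e + 1L):n
      S$state_i$g_exc <- S$state_i$g_exc + S$bufE[slot, ii]
      S$state_i$g_inh <- S$state_i$g_inh + S$bufI[slot, ii]
    }
    S$bufE[slot, ] <- 0; S$bufI[slot, ] <- 0

    # 2. external drive
    I_e <- I_bg_e
    if (length(ep_mask) && t_prev >= ep$onset && t_prev < ep$offset)
      I_e[ep_mask] <- I_e[ep_mask] + ep$amplitude

    # 3. step neurons, block by block (elementwise: partition-invariant)
    spikes <- integer(0)
    for (b in blocks_e) {
      sub <- step_neurons(slice_state(S$state_e, b), I_e[b], dt, prep$params_e)
      S$state_e <- merge_state(S$state_e, sub$state, b)
      spikes <- c(spikes, b[sub$spikes])
    }
    spikes_i <- integer(0)
    for (b in blocks_i) {
      sub <- step_neurons(slice_state(S$state_i, b), I_bg_i[b], dt, prep$params_i)
      S$state_i <- merge_state(S$state_i, sub$state, b)
      spikes_i <- c(spikes_i, b[sub$spikes])
    }
    spikes <- c(spikes, spikes_i + n_e)   # global ids, ascending
    t_now <- t_prev + dt
    S$state_e$t <- t_now
    if (prep$n_i > 0) S$state_i$t <- t_now

    if (length(spikes)) {
      # 4. probabilistic delivery on every outgoing synapse
      sidx <- unlist(prep$out_syn[spikes], use.names = FALSE)
      if (length(sidx)) {
        ctr <- S$spike_count[prep$syn_pre[sidx]]
        hit <- counter_runif(seed, prep$syn_id[sidx], ctr) < S$p[sidx]
        hidx <- sidx[hit]
        if (length(hidx)) {
          tgt_slot <- ((g + prep$delay_steps[hidx] - 1L) %% prep$n_slots) + 1L
          lin <- tgt_slot + prep$n_slots * (prep$syn_post[hidx] - 1L)
          exc <- prep$syn_exc[hidx]
          if (any(exc)) {
            acc <- rowsum(S$w[hidx[exc]], lin[exc])
            S$bufE[as.integer(rownames(acc))] <-
              S$bufE[as.integer(rownames(acc))] + acc[, 1L]
          }
          if (any(!exc)) {
            acc <- rowsum(S$w[hidx[!exc]], lin[!exc])
            S$bufI[as.integer(rownames(acc))] <-
              S$bufI[as.integer(rownames(acc))] + acc[, 1L]
          }
        }
      }

      # 5. online STDP (nearest-neighbour; last_spike frozen at pre-step values)
      if (rule$enabled && rule$kind == "STDP") {
        pot <- unlist(prep$plastic_by_post[spikes], use.names = FALSE)
        if (length(pot)) {
          dtp <- t_now - S$last_spike[prep$syn_pre[pot]]
          ok <- is.finite(dtp) & dtp > 0 & dtp <= rule$pair_window * rule$tau_plus
          if (any(ok)) {
            i2 <- pot[ok]
            S$w[i2] <- pmin(pmax(S$w[i2] + rule$A_plus * exp(-dtp[ok] / rule$tau_plus),
                                 rule$w_min), rule$w_max)
          }
        }
        dep <- unlist(prep$plastic_by_pre[spikes], use.names = FALSE)
        if (length(dep)) {
          dtd <- S$last_spike[prep$syn_post[dep]] - t_now   # <= 0
          ok <- is.finite(dtd) & dtd < 0 & -dtd <= rule$pair_window * rule$tau_minus
          if (any(ok)) {
            i2 <- dep[ok]
            S$w[i2] <- pmin(pmax(S$w[i2] - rule$A_minus * exp(dtd[ok] / rule$tau_minus),
                                 rule$w_min), rule$w_max)
          }
        }
      }

      S$spike_count[spikes] <- S$spike_count[spikes] + 1L
      S$last_spike[spikes] <- t_now
      S$freq_counts[spikes] <- S$freq_counts[spikes] + 1L
      if (glia_on) {
        esp <- spikes[spikes <= n_e]
        if (length(esp))
          S$dom_spikes <- S$dom_spikes +
            tabulate(prep$cell_astro[esp], nbins = prep$n_a)
      }
      sp_cells[[k]] <- spikes
      sp_times[[k]] <- rep(t_now, length(spikes))
    }

    # 6. frequency-dependent plasticity at its cadence
    if (rule$enabled && rule$kind == "FREQ" && g %% freq_steps == 0L) {
      rate <- S$freq_counts * 1000 / (freq_steps * dt)
      pl <- unlist(prep$plastic_by_pre, use.names = FALSE)
      if (length(pl)) {
        S$w[pl] <- pmin(pmax(S$w[pl] + rule$gain * (rate[prep$syn_pre[pl]] - rule$theta_r),
                             rule$w_min), rule$w_max)
      }
      S$freq_counts[] <- 0L
    }

    # 7. astrocytes: Ca dynamics and release-probability modulation
    if (glia_on && g %% stride == 0L) {
      S$astro <- step_astro(S$astro, prep$astro, prep$gj, S$dom_spikes,
                            dt * stride)
      S$dom_spikes[] <- 0L
      idx <- which(!is.na(prep$domains$syn_astro) &
                     prep$syn_class %in% config$modulate_classes)
      if (length(idx))
        S$p[idx] <- release_prob(S$astro$Ca[prep$domains$syn_astro[idx]],
                                 prep$astro)
      if (g %% ca_every_steps == 0L) {
        ca_rec[[length(ca_rec) + 1L]] <- S$astro$Ca
        ca_t <- c(ca_t, t_now)
      }
    }

    S$step <- g
  }

  list(state = S,
       cells = unlist(sp_cells, use.names = FALSE) %||% integer(0),
       times = unlist(sp_times, use.names = FALSE) %||% numeric(0),
       ca = if (length(ca_rec)) do.call(rbind, ca_rec) else
         matrix(numeric(0), 0, max(prep$n_a, 0)),
       ca_t = ca_t)
}

assemble_result <- function(loop, prep, config, network, t0, t_end, workers,
                            wall) {
  cells <- loop$cells; times <- loop$times
  is_e <- cells <= prep$n_e
  raster_e <- spike_raster(cells[is_e], times[is_e], prep$n_e, t_end)
  raster_i <- spike_raster(cells[!is_e] - prep$n_e, times[!is_e], prep$n_i, t_end)
  syn <- data.frame(pre = prep$syn_pre, post = prep$syn_post,
                    w = loop$state$w, delay = prep$syn_delay,
                    p = loop$state$p, class = prep$syn_class,
                    syn_id = prep$syn_id, stringsAsFactors = FALSE)
  class(syn) <- c("glia_connectivity", "data.frame")
  dur <- t_end - t0
  metrics <- list(
    F_e = if (dur > 0) sum(is_e) / prep$n_e * 1000 / dur else 0,
    F_i = if (dur > 0 && prep$n_i > 0) sum(!is_e) / prep$n_i * 1000 / dur else 0,
    synchronization = if (dur > 0 && length(unique(cells[is_e])) >= 2)
      synchronization(raster_e) else NA_real_
  )
  structure(list(
    raster_e = raster_e, raster_i = raster_i,
    ca = loop$ca, ca_t = loop$ca_t,
    connectivity = syn,
    metrics = metrics,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      workers = workers, t0 = t0, t_end = t_end,
                      package_version = as.character(utils::packageVersion("gliasim")),
                      wall_time_s = wall),
    checkpoint = structure(list(state = loop$state, prep = prep,
                                config = config, network = network,
                                config_hash = config_hash(config)),
                           class = "glia_checkpoint"),
    config = config
  ), class = "glia_result")
}

#' Simulate a configured network
#'
#' Builds the network from the configuration (or reuses a supplied one),
#' runs the time loop over `[0, T_total]`, and returns the spike rasters,
#' astrocyte Ca trajectory, final connectivity, summary metrics, provenance
#' and a resumable checkpoint.  For a fixed seed the result is bit-identical
#' for any `workers` value.
#'
#' @param config a `glia_config`.
#' @param ep optional `glia_ep` external pattern.
#' @param workers number of partition blocks (defaults to `config$workers`).
#' @param connectivity optional `glia_connectivity` overriding the generated
#'   weights/release probabilities (e.g. a memorized matrix for recall).
#' @param network optional prebuilt `glia_network` (skips rebuilding; the
#'   configuration seed still controls initial conditions).
#' @param T_total run duration override (ms).
#' @param ca_every_steps astrocyte Ca recording cadence, in steps.
#' @return A `glia_result`.
#' @examples
#' cfg <- network_config(n_e = 10, n_i = 2, n_a = 1, T_total = 20, seed = 1,
#'                       connectivity = list(
#'                         ee = list(rule = "BSD",
#'                                   params = topology_params(n_out = 2))))
#' res <- simulate_network(cfg)
#' @export
simulate_network <- function(config, ep = NULL, workers = config$workers,
                             connectivity = NULL, network = NULL,
                             T_total = config$T_total,
                             ca_every_steps = NULL) {
  config <- validate_config(config)
  if (!is.null(ep) && length(ep$mask) != config$n_e)
    stop(sprintf("external pattern mask length %d does not match n_e = %d",
                 length(ep$mask), config$n_e), call. = FALSE)
  t_start <- proc.time()[["elapsed"]]
  if (is.null(network)) network <- build_network(config)
  prep <- prepare_sim(network, config, connectivity)
  S <- init_sim_state(prep, config)
  n_steps <- as.integer(floor(T_total / config$dt + 1e-9))
  loop <- run_loop(S, prep, config, ep, n_steps, workers, ca_every_steps)
  wall <- proc.time()[["elapsed"]] - t_start
  assemble_result(loop, prep, config, network, 0, n_steps * config$dt,
                  workers, wall)
}

#' Resume a simulation from a checkpoint
#'
#' Continues the time loop for `extra_T` more milliseconds from the exact
#' state stored in the checkpoint (membrane and astrocyte state, pending
#' synaptic events, plasticity traces, release-stream counters, weights).
#' A run of duration `T1 + T2` and a run of `T1` resumed for `T2` produce
#' bit-identical event lists.  Resuming under a configuration whose hash
#' differs from the checkpoint's is refused.
#'
#' @param checkpoint a `glia_checkpoint` (from a `glia_result`).
#' @param extra_T additional duration (ms, >= 0).
#' @param ep optional `glia_ep` (patterns are defined in absolute time).
#' @param workers partition blocks for the resumed segment.
#' @param config optional configuration to check against the checkpoint.
#' @param ca_every_steps astrocyte Ca recording cadence, in steps.
#' @return A `glia_result` covering the resumed segment (absolute times).
#' @export
resume <- function(checkpoint, extra_T, ep = NULL,
                   workers = checkpoint$config$workers, config = NULL,
                   ca_every_steps = NULL) {
  if (!inherits(checkpoint, "glia_checkpoint"))
    stop("not a checkpoint", call. = FALSE)
  if (!is.null(config) && !identical(config_hash(config), checkpoint$config_hash))
    stop("refusing to resume: configuration hash mismatch", call. = FALSE)
  cfg <- checkpoint$config
  prep <- checkpoint$prep
  t0 <- checkpoint$state$step * cfg$dt
  n_steps <- as.integer(floor(extra_T / cfg$dt + 1e-9))
  t_start <- proc.time()[["elapsed"]]
  loop <- run_loop(checkpoint$state, prep, cfg, ep, n_steps, workers,
                   ca_every_steps)
  wall <- proc.time()[["elapsed"]] - t_start
  assemble_result(loop, prep, cfg, checkpoint$network, t0,
                  (checkpoint$state$step + n_steps) * cfg$dt, workers, wall)
}

#' Worker-count optimization scan (Mode I)
#'
#' Runs a short probe simulation at each candidate worker count, records the
#' runtimes, and returns the performance curve (performance = 1/runtime)
#' with `k_opt = argmax` (smallest k on ties).  All probes must produce
#' identical event lists -- the partition-invariance contract; a probe that
#' errors is marked failed and excluded from the argmax.
#'
#' @param config a `glia_config`.
#' @param k_values integer vector of candidate worker counts.
#' @param T_probe probe duration (ms).
#' @param ep optional external pattern for the probes.
#' @return A `glia_perfcurve` data frame (`workers`, `runtime_s`,
#'   `performance`, `ok`) with attribute `k_opt`.
#' @export
worker_scan <- function(config, k_values, T_probe = 50, ep = NULL) {
  stopifnot(length(k_values) >= 1, T_probe > 0)
  runtimes <- rep(NA_real_, length(k_values))
  rasters <- vector("list", length(k_values))
  for (j in seq_along(k_values)) {
    res <- tryCatch(
      simulate_network(config, ep = ep, workers = k_values[j],
                       T_total = T_probe),
      error = function(e) NULL)
    if (!is.null(res)) {
      runtimes[j] <- res$provenance$wall_time_s
      rasters[[j]] <- res$raster_e
    }
  }
  ok <- !is.na(runtimes)
  ref <- which(ok)[1L]
  if (!is.na(ref)) {
    for (j in which(ok)) {
      if (!isTRUE(all.equal(rasters[[j]], rasters[[ref]], tolerance = 0)))
        stop("partition-invariance violation: probe event lists differ",
             call. = FALSE)
    }
  }
  perf <- ifelse(ok & runtimes > 0, 1 / runtimes, NA_real_)
  k_opt <- if (any(ok)) {
    best <- which(ok)[order(-perf[ok], k_values[ok])]  # smallest k on ties
    k_values[best[1L]]
  } else NA_integer_
  out <- data.frame(workers = k_values, runtime_s = runtimes,
                    performance = perf, ok = ok)
  attr(out, "k_opt") <- k_opt
  class(out) <- c("glia_perfcurve", "data.frame")
  out
}
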