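# Network configuration: the single declarative object everything else reads.
# The defaults are a desk-scale surrogate of a hippocampal CA1-like circuit:
# 100 e-neurons on a 250-um disc, 25 fast-spiking i-neurons on a 200-um disc,
# 9 astrocytes, bell-shaped-density wiring in all four classes.

#' Neuron membrane parameters
#'
#' Hodgkin-Huxley single-compartment parameters.  Two named presets are
#' provided: `"hh"` (classic squid-axon constants, used as the e-neuron
#' surrogate) and `"wb"` (Wang-Buzsaki fast-spiking interneuron).  Any field
#' can be overridden.
#'
#' @param preset `"hh"` or `"wb"`.
#' @param ... named overrides of individual fields (`C_m`, `g_Na`, `g_K`,
#'   `g_L`, `E_Na`, `E_K`, `E_L`, `E_exc`, `E_inh`, `tau_exc`, `tau_inh`,
#'   `V_th`, `phi`).
#' @return A `glia_neuron_params` list.  Units: uF/cm^2, mS/cm^2, mV, ms.
#' @export
neuron_params <- function(preset = c("hh", "wb"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    hh = list(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
              E_Na = 50, E_K = -77, E_L = -54.4,
              E_exc = 0, E_inh = -75, tau_exc = 2, tau_inh = 10,
              V_th = 0, phi = 1, kinetics = "hh"),
    wb = list(C_m = 1, g_Na = 35, g_K = 9, g_L = 0.1,
              E_Na = 55, E_K = -90, E_L = -65,
              E_exc = 0, E_inh = -75, tau_exc = 2, tau_inh = 10,
              V_th = 0, phi = 5, kinetics = "wb"))
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  stopifnot(p$C_m > 0, p$g_Na >= 0, p$g_K >= 0, p$g_L >= 0,
            p$tau_exc > 0, p$tau_inh > 0)
  structure(p, class = "glia_neuron_params")
}

#' Astrocyte calcium-dynamics parameters
#'
#' Two-variable Li-Rinzel-type IP3-receptor / SERCA / leak scheme with an
#' explicit IP3 pool and direct Ca^2+ gap-junction exchange.  Rates are per
#' millisecond; concentrations in uM.  `ip3_gain` is the IP3 increment per
#' covered presynaptic spike; `p0`, `p_max`, `K_Ca`, `n_H` parametrise the
#' sigmoid mapping from Ca to synaptic release probability.
#'
#' @param ... named overrides of the default fields.
#' @return A `glia_astro_params` list.
#' @export
astro_params <- function(...) {
  p <- list(
    c0 = 2.0,       # total free Ca per cytosol volume (uM)
    c1 = 0.185,     # ER/cytosol volume ratio
    v1 = 6e-3,      # max IP3R channel flux (1/ms)
    v2 = 0.11e-3,   # Ca leak from ER (1/ms)
    v3 = 0.9e-3,    # max SERCA pump rate (uM/ms)
    k3 = 0.1,       # SERCA half-activation (uM)
    d1 = 0.13,      # IP3 dissociation constant (uM)
    d2 = 1.049,     # Ca inactivation dissociation constant (uM)
    d3 = 0.9434,    # IP3 dissociation constant for Q2 (uM)
    d5 = 0.08234,   # Ca activation dissociation constant (uM)
    a2 = 0.2e-3,    # inactivation binding rate (1/(uM ms))
    ip3_baseline = 0.16,   # resting IP3 (uM), below the oscillatory range
    ip3_gain = 1.5e-3,     # IP3 increment per covered presynaptic spike (uM)
    tau_ip3 = 7000,        # IP3 degradation time constant (ms)
    g_gj = 5e-4,           # gap-junction Ca exchange rate (1/ms)
    p0 = 0.2, p_max = 0.8, K_Ca = 0.3, n_H = 2,
    Ca0 = 0.07, q0 = 0.8   # initial cytosolic Ca (uM) and IP3R gate
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  stopifnot(p$p0 >= 0, p$p0 <= p$p_max, p$p_max <= 1, p$K_Ca > 0, p$n_H >= 1,
            p$tau_ip3 > 0, p$g_gj >= 0)
  structure(p, class = "glia_astro_params")
}

default_connectivity <- function() {
  list(
    ee = list(rule = "BSD", params = topology_params(w_uniform = 0.003,
                                                     sigma_d = 200, n_out = 30)),
    ei = list(rule = "BSD", params = topology_params(w_uniform = 0.010,
                                                     sigma_d = 200, n_out = 12)),
    ie = list(rule = "BSD", params = topology_params(w_uniform = 0.010,
                                                     sigma_d = 200, n_out = 40)),
    ii = list(rule = "BSD", params = topology_params(w_uniform = 0.010,
                                                     sigma_d = 200, n_out = 10))
  )
}

#' Create a network/simulation configuration
#'
#' Collects every declarative setting of a run: population sizes and radii,
#' per-class connectivity rules, neuron and astrocyte biophysics, plasticity
#' rule, run duration, step size, seed and worker count.
#'
#' @param n_e,n_i,n_a population sizes (e-neurons, i-neurons, astrocytes).
#' @param R_e,R_i,R_a population disc radii (um).
#' @param connectivity named list with entries `ee`, `ei`, `ie`, `ii`, each
#'   `list(rule = "BSS"|"BSD"|"NONE", params = topology_params(...))`.
#' @param neuron_e,neuron_i [neuron_params()] for the two populations.
#' @param astro [astro_params()].
#' @param plasticity a [plasticity_rule()].
#' @param T_total run duration (ms).
#' @param dt integration step (ms).
#' @param seed integer master seed (drives placement, wiring, initial state
#'   and every synaptic release stream).
#' @param workers number of partition blocks (>= 1).
#' @param I_bg_e,I_bg_i baseline injected current (uA/cm^2), scalar or
#'   per-cell vector.
#' @param glia_enabled logical: integrate astrocytes and let them modulate
#'   release probability.
#' @param modulate_classes which synapse classes astrocytes modulate
#'   (subset of `c("ee", "ei")`).
#' @param gap_k gap-junction nearest-neighbour count.
#' @param astro_stride astrocyte update cadence in neuronal steps (>= 1).
#' @param layout `"disc"` or `"ring"` cell placement.
#' @param V_init_range range of the uniform initial-voltage jitter (mV).
#' @return A validated `glia_config` list.
#' @examples
#' cfg <- network_config(n_e = 20, n_i = 5, n_a = 2, T_total = 50, seed = 1)
#' @export
network_config <- function(n_e = 100, n_i = 25, n_a = 9,
                           R_e = 250, R_i = 200, R_a = 250,
                           connectivity = default_connectivity(),
                           neuron_e = neuron_params("hh"),
                           neuron_i = neuron_params("wb"),
                           astro = astro_params(),
                           plasticity = plasticity_rule("NONE"),
                           T_total = 200, dt = 0.05, seed = 1L, workers = 1L,
                           I_bg_e = 0, I_bg_i = 0,
                           glia_enabled = n_a > 0,
                           modulate_classes = c("ee", "ei"),
                           gap_k = 2L, astro_stride = 1L,
                           layout = "disc", V_init_range = c(-70, -60)) {
  cfg <- structure(list(
    n_e = as.integer(n_e), n_i = as.integer(n_i), n_a = as.integer(n_a),
    R_e = R_e, R_i = R_i, R_a = R_a,
    connectivity = connectivity,
    neuron_e = neuron_e, neuron_i = neuron_i, astro = astro,
    plasticity = plasticity,
    T_total = T_total, dt = dt, seed = as.integer(seed),
    workers = as.integer(workers),
    I_bg_e = I_bg_e, I_bg_i = I_bg_i,
    glia_enabled = isTRUE(glia_enabled),
    modulate_classes = modulate_classes,
    gap_k = as.integer(gap_k), astro_stride = as.integer(astro_stride),
    layout = layout, V_init_range = V_init_range
  ), class = "glia_config")
  validate_config(cfg)
}

#' @rdname network_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "glia_config"))
    stop("not a 'glia_config' object", call. = FALSE)
  req <- c("n_e", "n_i", "T_total", "dt", "seed")
  for (f in req) {
    if (is.null(config[[f]]))
      stop(sprintf("configuration field '%s' is missing", f), call. = FALSE)
  }
  if (config$n_e < 0 || config$n_i < 0 || config$n_e + config$n_i < 1)
    stop("need n_e, n_i >= 0 and n_e + n_i >= 1", call. = FALSE)
  if (config$R_e <= 0 || config$R_i <= 0 || config$R_a <= 0)
    stop("population radii must be positive", call. = FALSE)
  if (config$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (config$T_total < 0) stop("T_total must be non-negative", call. = FALSE)
  if (config$workers < 1) stop("workers must be >= 1", call. = FALSE)
  if (config$astro_stride < 1) stop("astro_stride must be >= 1", call. = FALSE)
  if (config$glia_enabled && config$n_a < 1)
    stop("astrocyte modulation enabled but n_a = 0", call. = FALSE)
  if (!all(config$modulate_classes %in% c("ee", "ei")))
    stop("modulate_classes must be a subset of c('ee','ei')", call. = FALSE)
  config
}

# Canonical serialization: stable field order, full precision, class tags
# dropped.  Basis of the provenance hash.
config_canonical <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[order(names(x))]
    } else x
  }
  jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE, digits = NA)
}

#' Configuration provenance hash
#'
#' A short hexadecimal digest of the canonical serialization; changes when
#' any configuration field changes.  Used to refuse resuming a checkpoint
#' under an edited configuration.
#'
#' @param config a `glia_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a(as.character(config_canonical(config)))
}

#' Read / write configurations
#'
#' Configurations round-trip through YAML or JSON (chosen by file
#' extension).  Missing required fields are reported by name.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @param config a `glia_config` (for `save_config`).
#' @return `load_config` returns a validated `glia_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c("n_e", "n_i")) {
    if (is.null(raw[[f]]))
      stop(sprintf("configuration file %s: required field '%s' is missing",
                   path, f), call. = FALSE)
  }
  args <- list()
  simple <- c("n_e", "n_i", "n_a", "R_e", "R_i", "R_a", "T_total", "dt",
              "seed", "workers", "I_bg_e", "I_bg_i", "glia_enabled",
              "modulate_classes", "gap_k", "astro_stride", "layout",
              "V_init_range")
  for (f in simple) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$connectivity)) {
    conn <- default_connectivity()
    for (cl in names(raw$connectivity)) {
      spec <- raw$connectivity[[cl]]
      pars <- spec$params
      conn[[cl]] <- list(rule = spec$rule,
                         params = do.call(topology_params, as.list(pars)))
    }
    args$connectivity <- conn
  }
  if (!is.null(raw$neuron_e))
    args$neuron_e <- do.call(neuron_params, c(list(preset = raw$neuron_e$kinetics %||% "hh"),
                                              raw$neuron_e[setdiff(names(raw$neuron_e), "kinetics")]))
  if (!is.null(raw$neuron_i))
    args$neuron_i <- do.call(neuron_params, c(list(preset = raw$neuron_i$kinetics %||% "wb"),
                                              raw$neuron_i[setdiff(names(raw$neuron_i), "kinetics")]))
  if (!is.null(raw$astro)) args$astro <- do.call(astro_params, as.list(raw$astro))
  if (!is.null(raw$plasticity)) {
    pl <- as.list(raw$plasticity)
    pl$enabled <- NULL   # derived from kind, not a constructor argument
    args$plasticity <- do.call(plasticity_rule, pl)
  }
  do.call(network_config, args)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  obj <- unclass(config)
  obj$connectivity <- lapply(obj$connectivity, function(s)
    list(rule = s$rule, params = unclass(s$params)))
  obj$neuron_e <- unclass(obj$neuron_e)
  obj$neuron_i <- unclass(obj$neuron_i)
  obj$astro <- unclass(obj$astro)
  obj$plasticity <- unclass(obj$plasticity)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(obj, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
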