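# Network geometry and wiring.
#
# Three cell populations (e-neurons, i-neurons, astrocytes) live on concentric
# 2-D discs of radius R_e, R_i, R_a.  Neuronal wiring uses one of two
# distance-dependent rules per connection class (ee, ei, ie, ii):
#   BSS ("bell-shaped strength"): every presynaptic cell contacts a fixed
#     fraction of its nearest targets with Gaussian-of-distance weights.
#   BSD ("bell-shaped density"):  uniform weights, Gaussian-of-distance
#     connection probability normalised to a requested mean out-degree.
# Astrocytes tile the excitatory synapses into disjoint territories (each
# synapse follows its presynaptic e-cell to the nearest astrocyte) and couple
# to each other through a symmetric k-nearest-neighbour gap-junction graph.

#' Place cells uniformly on a disc
#'
#' Draws `n` independent positions uniformly over a disc (or, optionally, on a
#' ring of the given radius).  Positions are drawn from R's RNG; seed it (or
#' let [build_network()] do so) for reproducibility.
#'
#' @param n number of cells (>= 0).
#' @param radius disc radius in micrometres (> 0).
#' @param population tag, one of `"e"`, `"i"`, `"a"`.
#' @param layout `"disc"` (default) or `"ring"`.
#' @return A `glia_positions` data frame with columns `x`, `y` (um) and
#'   attributes `population` and `radius`.
#' @examples
#' set.seed(1)
#' pos <- place_cells(100, 250, "e")
#' max(sqrt(pos$x^2 + pos$y^2)) <= 250
#' @export
place_cells <- function(n, radius, population = c("e", "i", "a"),
                        layout = c("disc", "ring")) {
  population <- match.arg(population)
  layout <- match.arg(layout)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  n <- as.integer(n)
  theta <- stats::runif(n, 0, 2 * pi)
  r <- if (layout == "disc") radius * sqrt(stats::runif(n)) else rep(radius, n)
  out <- data.frame(x = r * cos(theta), y = r * sin(theta))
  attr(out, "population") <- population
  attr(out, "radius") <- radius
  class(out) <- c("glia_positions", "data.frame")
  out
}

#' Connectivity-rule parameters
#'
#' Parameter block for one connection class.  BSS uses `w_peak`, `sigma_w`
#' and `fraction`; BSD uses `w_uniform`, `sigma_d` and `n_out`.  Conduction
#' delay is `delay0 + d / velocity` for pre-post distance `d`.
#'
#' @param sigma_w Gaussian weight s.d. (um, BSS).
#' @param w_peak peak synaptic weight (mS/cm^2, BSS).
#' @param fraction connected fraction of nearest targets (BSS), in (0, 1].
#' @param w_uniform uniform synaptic weight (mS/cm^2, BSD).
#' @param sigma_d Gaussian density s.d. (um, BSD).
#' @param n_out requested mean out-degree (BSD), >= 1.
#' @param p_release baseline release probability in `[0, 1]`.
#' @param delay0 fixed delay component (ms).
#' @param velocity conduction velocity (um/ms).
#' @return A `glia_topology_params` list.
#' @export
topology_params <- function(sigma_w = 100, w_peak = 0.005, fraction = 0.5,
                            w_uniform = 0.003, sigma_d = 200, n_out = 30,
                            p_release = 1, delay0 = 1, velocity = 200) {
  stopifnot(sigma_w > 0, sigma_d > 0, fraction > 0, fraction <= 1,
            n_out >= 1, w_peak >= 0, w_uniform >= 0,
            p_release >= 0, p_release <= 1, delay0 >= 0, velocity > 0)
  structure(list(sigma_w = sigma_w, w_peak = w_peak, fraction = fraction,
                 w_uniform = w_uniform, sigma_d = sigma_d, n_out = n_out,
                 p_release = p_release, delay0 = delay0, velocity = velocity),
            class = "glia_topology_params")
}

cross_dist <- function(pre, post) {
  sqrt(outer(pre$x, post$x, "-")^2 + outer(pre$y, post$y, "-")^2)
}

same_population <- function(pre, post) {
  identical(attr(pre, "population"), attr(post, "population"))
}

new_connectivity <- function(pre, post, w, d, params, class) {
  data.frame(pre = pre, post = post, w = w,
             delay = params$delay0 + d / params$velocity,
             p = rep(params$p_release, length(pre)),
             class = rep(class, length(pre)),
             stringsAsFactors = FALSE)
}

finish_connectivity <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("glia_connectivity", "data.frame")
  df
}

#' Bell-shaped-strength (BSS) wiring
#'
#' Every presynaptic cell contacts exactly `floor(fraction * N_post)` of its
#' nearest postsynaptic cells (ties broken by cell index; autapses excluded
#' within a population).  Each synapse's weight is the Gaussian of the
#' pre-post distance, `w_peak * exp(-d^2 / (2 sigma_w^2))`.
#'
#' @param pre,post `glia_positions` of the presynaptic and postsynaptic
#'   populations.
#' @param params [topology_params()].
#' @param class connection class label (`"ee"`, `"ei"`, `"ie"`, `"ii"`).
#' @param pre_offset,post_offset index offsets converting local cell numbers
#'   to network-global ids.
#' @return A `glia_connectivity` data frame (`pre`, `post`, `w`, `delay`,
#'   `p`, `class`).
#' @export
build_bss <- function(pre, post, params, class,
                      pre_offset = 0L, post_offset = 0L) {
  n_pre <- nrow(pre); n_post <- nrow(post)
  if (n_pre < 1 || n_post < 1)
    stop("both populations must be non-empty", call. = FALSE)
  k <- floor(params$fraction * n_post)
  if (k < 1)
    stop("BSS: fraction * N_post < 1, no targets available", call. = FALSE)
  dmat <- cross_dist(pre, post)
  self <- same_population(pre, post)
  rows <- vector("list", n_pre)
  for (i in seq_len(n_pre)) {
    d <- dmat[i, ]
    cand <- seq_len(n_post)
    if (self) cand <- cand[cand != i]
    # nearest k, ties broken by cell index (order() is stable on the index)
    sel <- cand[order(d[cand])][seq_len(k)]
    rows[[i]] <- new_connectivity(rep(i + pre_offset, k), sel + post_offset,
                                  params$w_peak *
                                    exp(-d[sel]^2 / (2 * params$sigma_w^2)),
                                  d[sel], params, class)
  }
  finish_connectivity(do.call(rbind, rows))
}

#' Bell-shaped-density (BSD) wiring
#'
#' Each ordered pre-post pair is connected independently with probability
#' `q(d) = q0 * exp(-d^2 / (2 sigma_d^2))`, where `q0` is chosen so that the
#' population-mean expected out-degree equals `n_out`.  All realized synapses
#' carry the uniform weight `w_uniform`.  If the requested `n_out` would need
#' `q0 > 1` the call fails and reports the largest achievable mean out-degree
#' for the geometry.
#'
#' @inheritParams build_bss
#' @return A `glia_connectivity` data frame.
#' @export
build_bsd <- function(pre, post, params, class,
                      pre_offset = 0L, post_offset = 0L) {
  n_pre <- nrow(pre); n_post <- nrow(post)
  if (n_pre < 1 || n_post < 1)
    stop("both populations must be non-empty", call. = FALSE)
  dmat <- cross_dist(pre, post)
  kern <- exp(-dmat^2 / (2 * params$sigma_d^2))
  if (same_population(pre, post)) diag(kern) <- 0
  mean_kernel_degree <- sum(kern) / n_pre
  q0 <- params$n_out / mean_kernel_degree
  if (q0 > 1)
    stop(sprintf(paste0("BSD: requested mean out-degree %.3g needs q0 = %.3g > 1; ",
                        "the achievable maximum for this geometry is %.3g"),
                 params$n_out, q0, mean_kernel_degree), call. = FALSE)
  u <- matrix(stats::runif(length(kern)), n_pre, n_post)
  hit <- which(u < q0 * kern, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  d <- dmat[hit]
  finish_connectivity(new_connectivity(
    hit[, 1L] + pre_offset, hit[, 2L] + post_offset,
    rep(params$w_uniform, nrow(hit)), d, params, class))
}

#' Assign excitatory synapses to astrocyte territories
#'
#' Astrocytes occupy non-overlapping domains: every excitatory synapse
#' (class `ee` or `ei`) is covered by the astrocyte nearest to its
#' presynaptic e-cell, so the covered synapse set is partitioned by
#' construction.  Inhibitory synapses are never covered.
#'
#' @param a_pos astrocyte `glia_positions`.
#' @param syn `glia_connectivity` table with global synapse rows.
#' @param e_pos e-neuron `glia_positions` (global ids `1..n_e`).
#' @return A `glia_domains` list with `syn_astro` (per-synapse covering
#'   astrocyte id, `NA` when uncovered), `cell_astro` (per-e-cell nearest
#'   astrocyte), and `synapses` (list of synapse row indices per astrocyte).
#' @export
assign_astro_domains <- function(a_pos, syn, e_pos) {
  if (nrow(a_pos) < 1)
    stop("astrocyte modulation requires at least one astrocyte", call. = FALSE)
  d <- cross_dist(e_pos, a_pos)
  cell_astro <- max.col(-d, ties.method = "first")
  syn_astro <- rep(NA_integer_, nrow(syn))
  exc <- syn$class %in% c("ee", "ei")
  syn_astro[exc] <- cell_astro[syn$pre[exc]]
  structure(list(
    syn_astro = syn_astro,
    cell_astro = cell_astro,
    synapses = split(which(exc), factor(syn_astro[exc],
                                        levels = seq_len(nrow(a_pos))))
  ), class = "glia_domains")
}

#' Astrocyte gap-junction graph
#'
#' Symmetric k-nearest-neighbour graph: an edge is present when either
#' endpoint lists the other among its `k` nearest astrocytes.  Edges carry a
#' Ca^2+ exchange rate `g_gj` (1/ms).
#'
#' @param a_pos astrocyte `glia_positions`.
#' @param k neighbour count, `0 <= k < n_a` (k = 0 gives no coupling).
#' @param g_gj coupling rate constant (1/ms, >= 0).
#' @return A `glia_gapjunctions` data frame with columns `a`, `b` (`a < b`)
#'   and `g`.
#' @export
build_gap_junctions <- function(a_pos, k, g_gj) {
  n_a <- nrow(a_pos)
  if (k >= n_a)
    stop("gap junctions: k must be smaller than the number of astrocytes",
         call. = FALSE)
  stopifnot(g_gj >= 0)
  if (k == 0L || n_a < 2L) {
    return(structure(data.frame(a = integer(0), b = integer(0), g = numeric(0)),
                     class = c("glia_gapjunctions", "data.frame")))
  }
  d <- cross_dist(a_pos, a_pos)
  diag(d) <- Inf
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(n_a)) {
    nb <- order(d[i, ])[seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  structure(data.frame(a = pairs[, 1L], b = pairs[, 2L],
                       g = rep(g_gj, nrow(pairs))),
            class = c("glia_gapjunctions", "data.frame"))
}

#' Assemble the full network from a configuration
#'
#' Seeds R's RNG from `config$seed`, places the three populations, builds the
#' four neuronal connection classes with the configured rule, assigns
#' astrocyte domains and the gap-junction graph.  Global cell ids are
#' `1..n_e` for e-neurons and `n_e+1..n_e+n_i` for i-neurons; each synapse row
#' gets a global `syn_id` used to key its release-probability random stream.
#'
#' @param config a `glia_config`, see [network_config()].
#' @return A `glia_network` list: `config`, `pos_e`, `pos_i`, `pos_a`,
#'   `synapses`, `domains`, `gap_junctions`.
#' @export
build_network <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed %% .Machine$integer.max)
  pos_e <- place_cells(config$n_e, config$R_e, "e", config$layout)
  pos_i <- place_cells(config$n_i, config$R_i, "i", config$layout)
  pos_a <- place_cells(config$n_a, config$R_a, "a", config$layout)
  n_e <- config$n_e
  ends <- list(ee = list(pos_e, pos_e, 0L, 0L),
               ei = list(pos_e, pos_i, 0L, n_e),
               ie = list(pos_i, pos_e, n_e, 0L),
               ii = list(pos_i, pos_i, n_e, n_e))
  parts <- list()
  for (cl in names(ends)) {
    spec <- config$connectivity[[cl]]
    if (is.null(spec) || identical(spec$rule, "NONE")) next
    e <- ends[[cl]]
    if (nrow(e[[1]]) == 0 || nrow(e[[2]]) == 0) next
    builder <- switch(spec$rule, BSS = build_bss, BSD = build_bsd,
                      stop(sprintf("unknown connectivity rule '%s'", spec$rule),
                           call. = FALSE))
    parts[[cl]] <- builder(e[[1]], e[[2]], spec$params, cl, e[[3]], e[[4]])
  }
  syn <- if (length(parts)) do.call(rbind, parts) else
    new_connectivity(integer(0), integer(0), numeric(0), numeric(0),
                     topology_params(), character(0))
  rownames(syn) <- NULL
  syn$syn_id <- seq_len(nrow(syn))
  class(syn) <- c("glia_connectivity", "data.frame")
  domains <- NULL
  gj <- NULL
  if (config$n_a > 0) {
    domains <- assign_astro_domains(pos_a, syn, pos_e)
    gj <- build_gap_junctions(pos_a, min(config$gap_k, config$n_a - 1L),
                              config$astro$g_gj)
  }
  structure(list(config = config, pos_e = pos_e, pos_i = pos_i, pos_a = pos_a,
                 synapses = syn, domains = domains, gap_junctions = gj),
            class = "glia_network")
}
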