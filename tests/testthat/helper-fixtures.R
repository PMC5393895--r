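# Shared fixtures: small networks sized so a full test run stays fast.

small_connectivity <- function(w_ee = 0.003, w_ei = 0.01, w_ie = 0.01,
                               w_ii = 0.01, n_out = c(8, 4, 8, 2)) {
  list(
    ee = list(rule = "BSD", params = topology_params(w_uniform = w_ee,
                                                     sigma_d = 200, n_out = n_out[1])),
    ei = list(rule = "BSD", params = topology_params(w_uniform = w_ei,
                                                     sigma_d = 200, n_out = n_out[2])),
    ie = list(rule = "BSD", params = topology_params(w_uniform = w_ie,
                                                     sigma_d = 200, n_out = n_out[3])),
    ii = list(rule = "BSD", params = topology_params(w_uniform = w_ii,
                                                     sigma_d = 200, n_out = n_out[4]))
  )
}

small_config <- function(seed = 2, T_total = 80, n_e = 30, n_i = 8, n_a = 3,
                         ...) {
  network_config(n_e = n_e, n_i = n_i, n_a = n_a, T_total = T_total,
                 seed = seed, connectivity = small_connectivity(), ...)
}

# deterministic grid positions (no RNG) for geometry-sensitive checks
grid_positions <- function(xy, population = "e", radius = NULL) {
  out <- data.frame(x = xy[, 1], y = xy[, 2])
  attr(out, "population") <- population
  attr(out, "radius") <- radius %||% (max(sqrt(out$x^2 + out$y^2)) + 1)
  class(out) <- c("glia_positions", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-cell rate mean, the F oracle
brute_F <- function(raster) {
  N <- attr(raster, "N"); T_total <- attr(raster, "T_total")
  f <- vapply(seq_len(N), function(i) sum(raster$cell == i) / T_total * 1000,
              numeric(1))
  mean(f)
}
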