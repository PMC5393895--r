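# The simulation loop: determinism, partition invariance, checkpoint/resume,
# configuration and result I/O, and the worker scan.

test_that("a zero-duration run returns empty rasters and untouched weights", {
  cfg <- small_config(T_total = 0)
  res <- simulate_network(cfg)
  expect_equal(nrow(res$raster_e), 0L)
  expect_equal(nrow(res$raster_i), 0L)
  net <- build_network(cfg)
  expect_equal(res$connectivity$w, net$synapses$w)
})

test_that("identical seed and configuration give identical results", {
  cfg <- small_config(T_total = 60)
  ep <- ep_from_matrix(rep(c(TRUE, FALSE), length.out = 30), amplitude = 8)
  r1 <- simulate_network(cfg, ep = ep)
  r2 <- simulate_network(cfg, ep = ep)
  expect_identical(r1$raster_e, r2$raster_e)
  expect_identical(r1$connectivity, r2$connectivity)
})

test_that("the event list is invariant to the worker partition", {
  cfg <- small_config(T_total = 60, seed = 5,
                      plasticity = plasticity_rule("STDP"))
  ep <- ep_from_matrix(rep(TRUE, 30), amplitude = 8)
  base <- simulate_network(cfg, ep = ep, workers = 1)
  for (k in c(2, 3, 5)) {
    alt <- simulate_network(cfg, ep = ep, workers = k)
    expect_identical(alt$raster_e, base$raster_e)
    expect_identical(alt$raster_i, base$raster_i)
    expect_identical(alt$connectivity$w, base$connectivity$w)
    expect_identical(alt$ca, base$ca)
  }
})

test_that("a split run resumed from its checkpoint equals the unbroken run", {
  cfg <- small_config(T_total = 80, seed = 9)
  ep <- ep_from_matrix(rep(TRUE, 30), amplitude = 8)
  full <- simulate_network(cfg, ep = ep, T_total = 80)
  half <- simulate_network(cfg, ep = ep, T_total = 40)
  rest <- resume(half$checkpoint, 40, ep = ep)
  expect_identical(c(half$raster_e$cell, rest$raster_e$cell),
                   full$raster_e$cell)
  expect_identical(c(half$raster_e$t, rest$raster_e$t), full$raster_e$t)
  expect_identical(rest$connectivity$w, full$connectivity$w)
  expect_identical(rest$connectivity$p, full$connectivity$p)
  # zero-length resume adds no events
  none <- resume(half$checkpoint, 0, ep = ep)
  expect_equal(nrow(none$raster_e), 0L)
  # resuming under an edited configuration is refused
  cfg2 <- cfg; cfg2$T_total <- 999
  expect_error(resume(half$checkpoint, 10, config = cfg2), "hash")
})

test_that("configurations round-trip through YAML/JSON with named-field errors", {
  cfg <- small_config(seed = 4)
  yml <- tempfile(fileext = ".yaml")
  save_config(cfg, yml)
  back <- load_config(yml)
  expect_equal(config_hash(back), config_hash(cfg))
  jsn <- tempfile(fileext = ".json")
  save_config(cfg, jsn)
  expect_equal(config_hash(load_config(jsn)), config_hash(cfg))
  # a missing required field is reported by name
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_i = 5), bad)
  expect_error(load_config(bad), "'n_e'")
  # the hash reacts to any single-field change
  cfg2 <- cfg; cfg2$dt <- 0.025
  expect_false(config_hash(cfg2) == config_hash(cfg))
  cfg3 <- cfg; cfg3$connectivity$ee$params$w_uniform <- 0.004
  expect_false(config_hash(cfg3) == config_hash(cfg))
})

test_that("results round-trip bitwise through the plain-text container", {
  cfg <- small_config(T_total = 50, seed = 6)
  res <- simulate_network(cfg, ep = ep_from_matrix(rep(TRUE, 30), amplitude = 8))
  dir <- tempfile()
  save_result(res, dir)
  back <- load_result(dir)
  expect_identical(back$raster_e$cell, res$raster_e$cell)
  expect_identical(back$raster_e$t, res$raster_e$t)
  expect_identical(back$connectivity$w, res$connectivity$w)
  expect_identical(back$connectivity$p, res$connectivity$p)
  expect_identical(unname(back$ca), unname(res$ca))
  expect_equal(back$metrics$F_e, res$metrics$F_e)
  expect_equal(config_hash(back$config), config_hash(res$config))
})

test_that("the worker scan returns reciprocal-runtime performance and k_opt", {
  cfg <- small_config(T_total = 10, seed = 3)
  pc1 <- worker_scan(cfg, 1L, T_probe = 10)
  expect_equal(attr(pc1, "k_opt"), 1L)
  pc <- worker_scan(cfg, c(1L, 2L), T_probe = 10)
  expect_equal(pc$performance, 1 / pc$runtime_s)
  expect_true(attr(pc, "k_opt") %in% c(1L, 2L))
})

test_that("astrocyte modulation changes release probabilities during a run", {
  cfg <- small_config(T_total = 400, seed = 13, glia_enabled = TRUE,
                      astro_stride = 10)
  cfg$astro$ip3_gain <- 5e-3
  ep <- ep_from_matrix(rep(TRUE, 30), amplitude = 10)
  res <- simulate_network(cfg, ep = ep)
  covered <- !is.na(build_network(cfg)$domains$syn_astro)
  expect_true(any(res$connectivity$p[covered] != 1))
  expect_true(all(res$connectivity$p[!covered] == 1))
  p <- cfg$astro
  expect_true(all(res$connectivity$p >= p$p0 | res$connectivity$p == 1))
  expect_true(all(res$connectivity$p <= p$p_max | res$connectivity$p == 1))
})
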