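# Cell placement and the two distance-dependent wiring rules.

test_that("place_cells draws uniformly on the disc", {
  expect_equal(nrow(place_cells(0, 10, "e")), 0L)
  set.seed(1)
  pos <- place_cells(1000, 250, "e")
  expect_equal(nrow(pos), 1000L)
  expect_true(all(sqrt(pos$x^2 + pos$y^2) <= 250))
  # E(r^2) = R^2/2 on a uniform disc; var(r^2) = R^4/12
  set.seed(2)
  p2 <- place_cells(1e4, 1, "e")
  r2 <- p2$x^2 + p2$y^2
  expect_lt(abs(mean(r2) - 0.5), 3 * sqrt(1 / 12 / 1e4))
  expect_error(place_cells(10, -1, "e"), "radius")
  set.seed(3); a <- place_cells(50, 100, "i")
  set.seed(3); b <- place_cells(50, 100, "i")
  expect_identical(a, b)
})

test_that("BSS connects each cell to exactly floor(fraction * N_post) nearest targets", {
  set.seed(4)
  pre <- place_cells(60, 250, "e")
  post <- place_cells(100, 250, "i")
  syn <- build_bss(pre, post, topology_params(fraction = 0.5), "ei")
  deg <- table(syn$pre)
  expect_true(all(deg == 50))
  expect_equal(length(deg), 60L)
  # weights are the Gaussian of realized distance, exactly
  d <- sqrt((pre$x[syn$pre] - post$x[syn$post])^2 +
              (pre$y[syn$pre] - post$y[syn$post])^2)
  expect_equal(syn$w, 0.005 * exp(-d^2 / (2 * 100^2)), tolerance = 1e-12)
  # nearest-k selection agrees with brute force for a few cells
  for (i in c(1, 17, 60)) {
    di <- sqrt((pre$x[i] - post$x)^2 + (pre$y[i] - post$y)^2)
    expect_setequal(syn$post[syn$pre == i], order(di)[1:50])
  }
  # d = 0 gives the peak weight
  p0 <- grid_positions(cbind(0, 0), "e")
  p1 <- grid_positions(cbind(c(0, 3), c(0, 0)), "i")
  s0 <- build_bss(p0, p1, topology_params(fraction = 0.99, w_peak = 0.4), "ei")
  expect_equal(s0$w[s0$post == 1], 0.4)
  # flat-Gaussian limit: sigma_w >> distances makes all weights ~ w_peak
  big <- topology_params(sigma_w = 1e6 * 500, fraction = 0.5)
  sflat <- build_bss(pre, post, big, "ei")
  expect_lt(diff(range(sflat$w)) / big$w_peak, 1e-6)
  expect_error(build_bss(pre, post, topology_params(fraction = 0.001), "ei"),
               "no targets")
})

test_that("BSS excludes autapses within a population", {
  set.seed(5)
  pos <- place_cells(40, 100, "e")
  syn <- build_bss(pos, pos, topology_params(fraction = 0.5), "ee")
  expect_true(all(syn$pre != syn$post))
  expect_true(all(table(syn$pre) == 20))
})

test_that("BSD realizes uniform weights and a Gaussian connection density", {
  set.seed(6)
  pre <- place_cells(120, 250, "e")
  post <- place_cells(120, 250, "e")
  attr(post, "population") <- "i"   # distinct populations: all pairs eligible
  pars <- topology_params(w_uniform = 0.007, sigma_d = 150, n_out = 20)
  syn <- build_bsd(pre, post, pars, "ei")
  expect_true(all(syn$w == 0.007))
  # distance-binned connection frequencies against q(d) (chi-square oracle)
  dmat <- sqrt(outer(pre$x, post$x, "-")^2 + outer(pre$y, post$y, "-")^2)
  kern <- exp(-dmat^2 / (2 * 150^2))
  q0 <- 20 * 120 / sum(kern)
  q <- q0 * kern
  conn <- matrix(FALSE, 120, 120)
  conn[cbind(syn$pre, syn$post)] <- TRUE
  bins <- cut(dmat, stats::quantile(dmat, 0:10 / 10), include.lowest = TRUE)
  O <- tapply(conn, bins, sum)
  E <- tapply(q, bins, sum)
  V <- tapply(q * (1 - q), bins, sum)
  stat <- sum((O - E)^2 / V)
  expect_gt(stats::pchisq(stat, df = 10, lower.tail = FALSE), 0.01)
})

test_that("BSD out-degree matches n_out and flattens at large sigma_d", {
  set.seed(7)
  pre <- place_cells(100, 250, "e")
  post <- place_cells(100, 250, "i")
  pars <- topology_params(sigma_d = 1e6, n_out = 30)
  syn <- build_bsd(pre, post, pars, "ei")
  q0 <- 30 / 100   # flat kernel: q(d) ~ n_out / N_post
  se <- sqrt(100 * 100 * q0 * (1 - q0)) / 100
  expect_lt(abs(mean(table(factor(syn$pre, 1:100))) - 30), 3 * se)
  # distance independence: chi-square on distance-decile connection counts
  dmat <- sqrt(outer(pre$x, post$x, "-")^2 + outer(pre$y, post$y, "-")^2)
  conn <- matrix(FALSE, 100, 100); conn[cbind(syn$pre, syn$post)] <- TRUE
  bins <- cut(dmat, stats::quantile(dmat, 0:10 / 10), include.lowest = TRUE)
  O <- tapply(conn, bins, sum); n_b <- tapply(conn, bins, length)
  stat <- sum((O - n_b * q0)^2 / (n_b * q0 * (1 - q0)))
  expect_gt(stats::pchisq(stat, df = 10, lower.tail = FALSE), 0.01)
  # infeasible n_out reports the achievable maximum
  err <- tryCatch(build_bsd(pre, post, topology_params(sigma_d = 50, n_out = 90),
                            "ei"),
                  error = conditionMessage)
  expect_match(err, "achievable maximum")
  # degenerate single-pair case: q0 = 1 forces the synapse
  a <- grid_positions(cbind(0, 0), "e"); b <- grid_positions(cbind(0, 0), "i")
  s1 <- build_bsd(a, b, topology_params(n_out = 1), "ei")
  expect_equal(nrow(s1), 1L)
})

test_that("astrocyte domains tile the excitatory synapses disjointly", {
  set.seed(8)
  cfg <- small_config()
  net <- build_network(cfg)
  dom <- net$domains
  exc <- which(net$synapses$class %in% c("ee", "ei"))
  inh <- which(net$synapses$class %in% c("ie", "ii"))
  covered <- unlist(dom$synapses, use.names = FALSE)
  expect_setequal(covered, exc)                      # completeness
  expect_equal(anyDuplicated(covered), 0L)           # disjointness
  expect_true(all(is.na(dom$syn_astro[inh])))        # ii/ie never covered
  # single astrocyte gets everything
  a1 <- place_cells(1, 10, "a")
  d1 <- assign_astro_domains(a1, net$synapses, net$pos_e)
  expect_setequal(d1$synapses[[1]], exc)
  # nearest-astrocyte geometry
  a2 <- grid_positions(cbind(c(-1, 1), c(0, 0)), "a")
  e1 <- grid_positions(cbind(0.9, 0), "e")
  syn1 <- data.frame(pre = 1L, post = 1L, w = 1, delay = 1, p = 1,
                     class = "ee", syn_id = 1L)
  d2 <- assign_astro_domains(a2, syn1, e1)
  expect_equal(d2$syn_astro, 2L)
  expect_error(assign_astro_domains(place_cells(0, 1, "a"), syn1, e1),
               "astrocyte")
})

test_that("gap-junction graph is a symmetric k-nearest-neighbour union", {
  a2 <- grid_positions(cbind(c(0, 5), c(0, 0)), "a")
  g <- build_gap_junctions(a2, 1, 1e-3)
  expect_equal(nrow(g), 1L)
  expect_true(all(g$a < g$b))
  # 5 on a line with k = 1: a chain of 4 edges (brute-force nearest neighbour)
  line <- grid_positions(cbind(c(0, 1, 2.1, 3.3, 4.6), rep(0, 5)), "a")
  gl <- build_gap_junctions(line, 1, 1e-3)
  expect_equal(nrow(gl), 4L)
  expect_equal(gl$a, 1:4); expect_equal(gl$b, 2:5)
  expect_error(build_gap_junctions(a2, 2, 1e-3), "smaller")
})

test_that("network assembly is bit-reproducible for a fixed seed", {
  n1 <- build_network(small_config(seed = 11))
  n2 <- build_network(small_config(seed = 11))
  expect_identical(n1$synapses, n2$synapses)
  expect_identical(n1$pos_e, n2$pos_e)
  expect_false(identical(build_network(small_config(seed = 12))$synapses,
                         n1$synapses))
})
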