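# Astrocyte Ca dynamics, IP3 drive and the Ca -> release-probability map.

test_that("calcium is constant when all fluxes are off", {
  p <- astro_params(v1 = 0, v2 = 0, v3 = 0, g_gj = 0)
  s <- astro_state(3, p)
  expect_equal(ca_fluxes(s, p, NULL), rep(0, 3))
  s2 <- step_astro(s, p, NULL, 0, 1)
  expect_equal(s2$Ca, s$Ca)
  s$Ca[1] <- -0.1
  expect_error(ca_fluxes(s, p, NULL), "negative")
})

test_that("gap-junction exchange conserves total calcium", {
  p <- astro_params(v1 = 0, v2 = 0, v3 = 0, g_gj = 2e-3)
  pos <- grid_positions(cbind(c(0, 10), c(0, 0)), "a")
  gj <- build_gap_junctions(pos, 1, p$g_gj)
  s <- astro_state(2, p)
  s$Ca <- c(1.0, 0.2)
  tot0 <- sum(s$Ca)
  for (k in 1:2000) s <- step_astro(s, p, gj, c(0, 0), 1)
  expect_equal(sum(s$Ca), tot0, tolerance = 1e-10)
  expect_lt(abs(s$Ca[1] - s$Ca[2]), 1e-3)   # equilibration
})

test_that("the oscillator's period matches a high-accuracy reference within 5%", {
  p <- astro_params(ip3_baseline = 0.4)      # oscillatory IP3
  st <- astro_state(1, p)
  dt <- 1; n <- 80000
  ca <- numeric(n)
  for (k in seq_len(n)) { st <- step_astro(st, p, NULL, 0, dt); ca[k] <- st$Ca }
  peaks <- function(x, tt) {
    i <- which(diff(sign(diff(x))) == -2) + 1
    tt[i][x[i] > mean(x) + 0.2 * stats::sd(x)]
  }
  tt <- seq_len(n) * dt
  keep <- tt > 25000
  per_pkg <- mean(diff(peaks(ca[keep], tt[keep])))
  f <- function(t, y, parms) {
    s <- structure(list(Ca = y[1], IP3 = 0.4, q = y[2]),
                   class = "glia_astro_state")
    a_q <- p$a2 * p$d2 * (0.4 + p$d1) / (0.4 + p$d3)
    list(c(ca_fluxes(s, p, NULL), a_q * (1 - y[2]) - p$a2 * y[1] * y[2]))
  }
  out <- deSolve::lsoda(c(p$Ca0, p$q0), seq(0, 80000, by = 10), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  okeep <- out[, 1] > 25000
  per_ref <- mean(diff(peaks(out[okeep, 2], out[okeep, 1])))
  expect_lt(abs(per_pkg - per_ref) / per_ref, 0.05)
})

test_that("IP3 jumps by the configured gain per spike and relaxes to baseline", {
  p <- astro_params(ip3_gain = 2e-3, tau_ip3 = 50)
  s <- astro_state(1, p)
  s1 <- step_astro(s, p, NULL, 1L, 1e-9)    # one spike, negligible decay
  expect_equal(s1$IP3 - p$ip3_baseline, 2e-3, tolerance = 1e-9)
  expect_equal(ip3_drive(c(0L, 3L), p), c(0, 6e-3))
  # relaxation: elevated IP3 decays back with tau_ip3
  s$IP3 <- p$ip3_baseline + 0.2
  for (k in 1:500) s <- step_astro(s, p, NULL, 0L, 1)
  expect_lt(abs(s$IP3 - p$ip3_baseline), 0.2 * exp(-500 / 50) + 1e-9)
})

test_that("steady-state IP3 elevation is linear in domain spike rate", {
  p <- astro_params(ip3_gain = 1e-3, tau_ip3 = 40)
  elev <- function(spk_per_step) {
    s <- astro_state(1, p)
    for (k in 1:2000) s <- step_astro(s, p, NULL, spk_per_step, 1)
    s$IP3 - p$ip3_baseline
  }
  e1 <- elev(1L); e2 <- elev(2L)
  expect_equal(e2 / e1, 2, tolerance = 1e-6)
})

test_that("p(Ca) is a bounded, monotone sigmoid with the declared landmarks", {
  p <- astro_params(p0 = 0.2, p_max = 0.8, K_Ca = 0.3, n_H = 2)
  expect_equal(release_prob(0, p), 0.2)
  expect_equal(release_prob(0.3, p), 0.5)            # half-activation
  expect_lt(abs(release_prob(30, p) - 0.8), 1e-3)    # 100 K_Ca ~ saturation
  ca <- sort(stats::runif(200, 0, 10))
  pr <- release_prob(ca, p)
  expect_true(all(pr >= 0.2 & pr <= 0.8))
  expect_true(all(diff(pr) >= 0))
})

test_that("modulation touches only covered excitatory synapses", {
  syn <- data.frame(pre = c(1L, 1L, 31L, 31L), post = c(2L, 31L, 1L, 32L),
                    w = 0.01, delay = 1, p = c(0.9, 0.9, 0.9, 0.9),
                    class = c("ee", "ei", "ie", "ii"), syn_id = 1:4)
  a <- grid_positions(cbind(0, 0), "a")
  e <- grid_positions(cbind(c(0, 1), c(0, 0)), "e")
  dom <- assign_astro_domains(a, syn, e)
  p <- astro_params()
  st <- astro_state(1, p); st$Ca <- 0
  out <- apply_glia_modulation(dom, st, syn, p)
  expect_equal(out$p, c(p$p0, p$p0, 0.9, 0.9))       # ie/ii untouched
  out2 <- apply_glia_modulation(dom, st, syn, p, enabled = FALSE)
  expect_identical(out2, syn)
  out3 <- apply_glia_modulation(dom, st, syn, p, classes = "ei")
  expect_equal(out3$p, c(0.9, p$p0, 0.9, 0.9))
})
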