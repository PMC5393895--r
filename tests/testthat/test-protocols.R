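# External patterns and the three network readouts (F, coherence, recall C).

test_that("mask patterns drive exactly the masked cells", {
  ep0 <- ep_from_matrix(rep(FALSE, 10))
  expect_equal(sum(ep0$mask), 0L)
  ep1 <- ep_from_matrix(c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(which(ep1$mask), 1:5)
  ep2 <- ep_from_matrix(c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_length(intersect(which(ep1$mask), which(ep2$mask)), 0)
  expect_error(ep_from_matrix(rep(TRUE, 4), onset = 10, offset = 5), "onset")
  # engine refuses a mask that does not match the population
  expect_error(simulate_network(small_config(T_total = 1),
                                ep = ep_from_matrix(rep(TRUE, 7))),
               "n_e")
})

test_that("bitmap patterns map row-major pixels onto cells", {
  # all-white image: empty mask
  expect_equal(sum(ep_from_image(matrix(0, 4, 4), n_e = 16)$mask), 0L)
  # all-black 10x10 bitmap onto 100 cells: everything driven
  expect_equal(sum(ep_from_image(matrix(1, 10, 10), n_e = 100)$mask), 100L)
  # 2x2 with one black pixel onto 4 cells: exactly the mapped index
  img <- matrix(0, 2, 2); img[1, 2] <- 1   # row-major position 2
  m <- ep_from_image(img, n_e = 4)$mask
  expect_equal(which(m), 2L)
  # plain PBM round-trip
  pbm <- tempfile(fileext = ".pbm")
  writeLines(c("P1", "# comment", "3 2", "1 0 0", "0 0 1"), pbm)
  mp <- ep_from_image(pbm, n_e = 6)$mask
  expect_equal(which(mp), c(1L, 6L))
  # PNG round-trip
  pngf <- tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 1, 1, 1), 2, 2), pngf)   # one dark pixel
  expect_equal(sum(ep_from_image(pngf, n_e = 4)$mask), 1L)
  expect_error(ep_from_image(tempfile(fileext = ".txt"), 4), "unreadable")
})

test_that("mean frequency equals the brute-force per-cell average", {
  empty <- spike_raster(integer(0), numeric(0), 10, 1000)
  expect_equal(mean_frequency(empty), 0)
  two <- spike_raster(rep(1:2, each = 10), rep(seq(50, 950, 100), 2), 2, 1000)
  expect_equal(mean_frequency(two), 10)
  set.seed(21)
  r <- spike_raster(sample(1:50, 400, TRUE), stats::runif(400, 0, 2000),
                    50, 2000)
  expect_equal(mean_frequency(r), brute_F(r), tolerance = 1e-12)
  # 1/T scaling for a fixed spike set
  r2 <- spike_raster(r$cell, r$t, 50, 4000)
  expect_equal(mean_frequency(r2), mean_frequency(r) / 2, tolerance = 1e-12)
  # permutation of spike times within a cell changes nothing
  perm <- r[sample(nrow(r)), ]
  r3 <- spike_raster(perm$cell, perm$t, 50, 2000)
  expect_equal(mean_frequency(r3), mean_frequency(r), tolerance = 1e-12)
})

test_that("coherence is 1 for identical bins, 0 for disjoint, NA when undefined", {
  co <- spike_raster(rep(1:5, 3), rep(c(10, 50, 90), each = 5), 5, 100)
  expect_equal(synchronization(co, bin = 2), 1)
  dis <- spike_raster(c(1, 1, 2, 2), c(10, 50, 30, 70), 2, 100)
  expect_equal(synchronization(dis, bin = 2), 0)
  one <- spike_raster(c(1, 1), c(10, 50), 5, 100)
  expect_warning(s <- synchronization(one), "undefined")
  expect_true(is.na(s))
})

test_that("coherence of independent trains matches the Bernoulli-bin expectation", {
  bin <- 2; T_total <- 10000; L <- T_total / bin; rate <- 10
  p_bin <- rate * bin / 1000
  gen <- function(seed) {
    set.seed(seed)
    cells <- integer(0); times <- numeric(0)
    for (i in 1:20) {
      on <- which(stats::runif(L) < p_bin)
      cells <- c(cells, rep(i, length(on)))
      times <- c(times, (on - 0.5) * bin)
    }
    spike_raster(cells, times, 20, T_total)
  }
  s_obs <- synchronization(gen(101), bin = bin)
  # bootstrap oracle: distribution of the statistic under independence,
  # computed directly from Bernoulli bins without the package
  boot <- vapply(1:40, function(k) {
    set.seed(500 + k)
    X <- matrix(stats::rbinom(20 * L, 1, p_bin), 20, L)
    cross <- tcrossprod(X); cnt <- rowSums(X)
    kap <- cross / sqrt(outer(cnt, cnt))
    mean(kap[upper.tri(kap)], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(s_obs - mean(boot)), 3 * stats::sd(boot) + 3e-4)
})

test_that("recall quality is the cosine of per-neuron count vectors", {
  a <- spike_raster(c(1, 1, 2), c(10, 20, 30), 3, 100)
  expect_equal(recall_quality(a, a)$C, 1)
  b <- spike_raster(c(3, 3), c(15, 40), 3, 100)
  expect_equal(recall_quality(a, b)$C, 0)
  # counts (2,0) vs (1,1): C = 2 / (2 sqrt(2))
  r1 <- spike_raster(c(1, 1), c(5, 10), 2, 50)
  r2 <- spike_raster(c(1, 2), c(7, 9), 2, 50)
  expect_equal(recall_quality(r1, r2)$C, sqrt(0.5), tolerance = 1e-12)
  # symmetry and relabeling invariance
  expect_equal(recall_quality(r2, r1)$C, recall_quality(r1, r2)$C)
  relab <- function(r) spike_raster(3 - r$cell, r$t, 2, 50)
  expect_equal(recall_quality(relab(r1), relab(r2))$C,
               recall_quality(r1, r2)$C)
  # both silent: identical patterns, C = 1
  s0 <- spike_raster(integer(0), numeric(0), 4, 100)
  expect_equal(recall_quality(s0, s0)$C, 1)
  expect_error(recall_quality(a, spike_raster(1L, 1, 7, 100)), "population")
})
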