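test_that("knn_search respects the mode's index constraint", {
  m <- shadow_manifold(matrix(c(0, 1, 4, 9, 16)), times = 0:4)

  past <- knn_search(m, query_time = 3, k = 2, mode = "cccm")
  expect_equal(past$times, c(2L, 1L))
  expect_equal(past$distances, c(5, 8))

  full <- knn_search(m, query_time = 3, k = 2, mode = "ccm")
  expect_equal(full$times, c(2L, 4L))
  expect_equal(full$distances, c(5, 7))

  # exact duplicate in the past is the first neighbor with distance 0
  md <- shadow_manifold(matrix(c(2, 7, 9, 7, 1)), times = 0:4)
  dup <- knn_search(md, query_time = 3, k = 2, mode = "cccm")
  expect_equal(dup$times[1], 1L)
  expect_equal(dup$distances[1], 0)
})

test_that("insufficient candidates raise an error carrying the earliest admissible query", {
  m <- shadow_manifold(matrix(rnorm(6)), times = 0:5)
  err <- expect_error(knn_search(m, query_time = 2, k = 4, mode = "cccm"),
                      "not enough neighbors")
  expect_match(conditionMessage(err), "earliest admissible query_time is 4")
})

test_that("knn_search agrees with exhaustive search on random instances", {
  set.seed(202)
  for (rep in 1:15) {
    n <- sample(20:200, 1)
    E <- sample(1:4, 1)
    pts <- matrix(round(rnorm(n * E), 2), ncol = E)  # rounding forces ties
    m <- shadow_manifold(pts, times = seq_len(n) - 1L)
    for (mode in c("cccm", "ccm")) {
      k <- sample(2:6, 1)
      qt <- sample((k + 2):(n - 1), 1)
      got <- knn_search(m, qt, k, mode)
      want <- brute_knn(pts, m$times, qt, k, mode)
      expect_equal(got$times, want$times)
      expect_equal(got$distances, want$distances)
    }
  }
})

test_that("exponential weights follow the distance-ratio formula", {
  w <- neighbor_weights(c(1, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-15)
  expect_equal(w, c(0.7310585786300049, 0.2689414213699951), tolerance = 1e-12)

  expect_equal(neighbor_weights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(neighbor_weights(c(0, 0, 5)), c(0.5, 0.5, 0))

  set.seed(7)
  for (rep in 1:10) {
    d <- sort(abs(rnorm(6)))
    w <- neighbor_weights(d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(diff(w) <= 1e-15))
  }
  expect_error(neighbor_weights(c(2, 1)), "nondecreasing")
})

test_that("cross-map skill of a self-map on clean periodic data approaches 1", {
  x <- sin(seq(0, 8 * pi, length.out = 600))
  r <- cross_map(x, x, E = 3, tau = 2, mode = "cccm")
  expect_gt(r$rho, 0.999)
  expect_lt(r$mse, 1e-3)
})

test_that("independent white noise has near-zero skill in both modes", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(1000); y <- rnorm(1000)
    for (mode in c("cccm", "ccm")) {
      expect_lt(abs(cross_map(x, y, 5, 1, mode = mode)$rho), 0.1)
      expect_lt(abs(cross_map(y, x, 5, 1, mode = mode)$rho), 0.1)
    }
  }
})

test_that("the causalized valid range starts at the first time with E+1 past states", {
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100)
  for (E in c(2, 4)) for (tau in c(1, 3)) {
    r <- cross_map(x, y, E, tau, mode = "cccm")
    expect_equal(r$valid_range[1], (E - 1) * tau + E + 1)
    expect_equal(r$valid_range[2], 99)
    rc <- cross_map(x, y, E, tau, mode = "ccm")
    expect_equal(rc$valid_range[1], (E - 1) * tau)
  }
})

test_that("causalized predictions never depend on future samples", {
  set.seed(11)
  x <- rnorm(300); y <- rnorm(300)

  # truncating the future leaves earlier predictions bit-identical
  full <- cross_map(x, y, 4, 1, mode = "cccm")
  pre <- cross_map(x, y, 4, 1, mode = "cccm", library_length = 200)
  keep <- pre$predictions$time
  expect_equal(full$predictions$predicted[match(keep, full$predictions$time)],
               pre$predictions$predicted)

  # poisoning future manifold rows with NaN leaves the neighbor set unchanged
  m <- embed_series(x, 4, 1)
  qt <- 150
  poisoned <- m$points
  poisoned[m$times > qt, ] <- NaN
  mp <- shadow_manifold(poisoned, m$times, tau = 1)
  expect_equal(knn_search(mp, qt, 5, "cccm"), knn_search(m, qt, 5, "cccm"))

  # classic CCM, by contrast, does read the future
  full_ccm <- cross_map(x, y, 4, 1, mode = "ccm")
  pre_ccm <- cross_map(x, y, 4, 1, mode = "ccm", library_length = 200)
  keep <- pre_ccm$predictions$time
  expect_false(isTRUE(all.equal(
    full_ccm$predictions$predicted[match(keep, full_ccm$predictions$time)],
    pre_ccm$predictions$predicted)))
})

test_that("degenerate cross-map inputs are rejected", {
  expect_error(cross_map(rnorm(20), rnorm(21), 2, 1), "same length")
  expect_error(cross_map(rnorm(9), rep(1, 9), 2, 1, mode = "cccm"),
               "constant|too short")
  expect_error(cross_map(rnorm(100), rep(1, 100), 3, 1), "constant")
})

test_that("a one-point convergence grid reproduces the single cross-map call", {
  set.seed(31)
  vs <- simulate_system("ar_coupled", n = 400, seed = 31)
  cc <- convergence_curve(vs$X, vs$Y, 5, 1, mode = "cccm", lengths = 300)
  expect_equal(cc$rho_xy,
               cross_map(vs$X, vs$Y, 5, 1, library_length = 300)$rho)
  expect_equal(cc$rho_yx,
               cross_map(vs$Y, vs$X, 5, 1, library_length = 300)$rho)
})

test_that("skill converges upward with library length for a coupled system but not for noise", {
  vs <- simulate_system("ar_coupled", seed = 17)
  cc <- convergence_curve(vs$X, vs$Y, 5, 1, mode = "cccm",
                          lengths = c(256, 512, 1024, 2048))
  expect_true(all(diff(cc$rho_xy) > -0.05))      # nondecreasing within noise
  expect_gt(cc$rho_xy[4], cc$rho_xy[1] + 0.05)   # genuine growth

  set.seed(18)
  x <- rnorm(2048); y <- rnorm(2048)
  cn <- convergence_curve(x, y, 5, 1, mode = "cccm",
                          lengths = c(256, 512, 1024, 2048))
  expect_true(all(abs(cn$rho_xy) < 0.12))
  expect_lt(cn$rho_xy[4], 0.1)

  expect_error(convergence_curve(x, y, 5, 1, lengths = c(512, 256)),
               "strictly increasing")
  expect_error(convergence_curve(x, y, 5, 1, lengths = c(8, 256)),
               "library length 8")
})

test_that("directed information follows the Gaussian closed form", {
  expect_identical(di_from_rho(0), 0)
  # frozen from direct evaluation of -log2(1 - rho^2)/2
  expect_equal(di_from_rho(0.5067), 0.21403530897842118, tolerance = 1e-12)
  expect_equal(di_from_rho(0.99), 2.82554387950289909, tolerance = 1e-12)
  expect_error(di_from_rho(1), "< 1")
  expect_error(di_from_rho(-1.2), "< 1")

  rhos <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(di_from_rho(rhos)) > 0))
  expect_equal(di_from_rho(-rhos), di_from_rho(rhos))
})

test_that("noise attenuation of correlation matches the closed form empirically", {
  expect_identical(rho_under_error(2, 0), 1)
  expect_equal(rho_under_error(1, 1), 1 / sqrt(2), tolerance = 1e-12)
  sig <- rho_under_error(1, seq(0, 3, by = 0.25))
  expect_true(all(diff(sig) < 0))

  set.seed(99)
  y <- rnorm(10000, sd = 2)
  for (sigma_e in c(0.5, 2, 4)) {
    yhat <- y + rnorm(10000, sd = sigma_e)
    expect_lt(abs(cor(y, yhat) - rho_under_error(2, sigma_e)), 0.02)
  }

  # information through the implied Gaussian channel rises with SNR
  di <- di_from_rho(rho_under_error(1, c(2, 1, 0.5, 0.25, 0.1)))
  expect_true(all(diff(di) > 0))
})
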