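test_that("variable sets validate names, lengths and finiteness", {
  vs <- variable_set(a = 1:4, b = 5:8)
  expect_s3_class(vs, "variable_set")
  expect_equal(attr(vs, "n"), 4L)
  expect_error(variable_set(a = 1:4, a = 5:8), "duplicate")
  expect_error(variable_set(a = 1:4, b = 1:5), "lengths differ")
  expect_error(variable_set(a = c(1, NaN, 3)), "non-finite")
  expect_error(variable_set(1:4), "named")
})

test_that("joint embedding of one series reduces to the standardized embedding", {
  set.seed(40)
  vs <- variable_set(u = rnorm(60), v = rnorm(60))
  jm <- joint_embed(vs, "u", E = 3, tau = 2)
  em <- embed_series(standardize_series(vs$u), E = 3, tau = 2)
  expect_equal(unname(jm$points), unname(em$points))
  expect_equal(jm$times, em$times)
})

test_that("joint state vectors concatenate per-series blocks at one leading time", {
  vs <- variable_set(u = c(1, 2, 3, 4), v = c(10, 20, 30, 40))
  jm <- joint_embed(vs, c("u", "v"), E = 2, tau = 1)
  expect_equal(dim(jm$points), c(3L, 4L))

  # permuting the subset permutes column blocks but not pairwise distances
  set.seed(41)
  vs2 <- variable_set(a = rnorm(50), b = rnorm(50) * 100, c = rnorm(50))
  d1 <- dist(joint_embed(vs2, c("a", "b", "c"), 3, 1)$points)
  d2 <- dist(joint_embed(vs2, c("c", "a", "b"), 3, 1)$points)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)

  expect_error(joint_embed(vs2, character(0), 3, 1), "nonempty")
  expect_error(joint_embed(vs2, "zz", 3, 1), "unknown series")
})

test_that("conditional error variance vanishes for a copied target and is full for an independent one", {
  set.seed(42)
  # exact recurrences in the predictor pin every query to zero-distance
  # duplicates, so a copied target is reconstructed perfectly
  base <- rep(c(0.3, 1.2, -0.7, 2.1), 100)  # period 4 <= first query lag
  vs <- variable_set(P = base, Tcopy = base, Ind = rnorm(400))

  expect_lt(conditional_error_variance(vs, "Tcopy", "P", E = 3, tau = 1), 1e-20)

  v_ind <- mean(sapply(1:3, function(s) {
    set.seed(s)
    w <- variable_set(P = rnorm(600), Q = rnorm(600))
    conditional_error_variance(w, "Q", "P", E = 3, tau = 1) /
      mean((w$Q - mean(w$Q))^2)
  }))
  # an unpredictable target keeps essentially its own variance (the weighted
  # neighbor average adds a little of its own)
  expect_gt(v_ind, 0.8)
  expect_lt(v_ind, 1.6)
})

test_that("a shared driver's information makes the conditional error small", {
  vs <- simulate_system("confounded_trio", seed = 43)
  v <- conditional_error_variance(vs, "Y", "Z", E = 5, tau = 1)
  # the driver explains most, not all, of the target: the unpredictable own
  # component and finite neighbor density leave a small residual
  expect_lt(v / mean((vs$Y - mean(vs$Y))^2), 0.2)
})

test_that("conditional cCCM keeps a genuine link and collapses a confounded one", {
  # chain X -> Y with an irrelevant Z conditioned: ratio stays large
  ratios <- sapply(1:3, function(s) {
    set.seed(s)
    x <- rnorm(800)
    y <- c(0, 0.9 * x[-800]) + rnorm(800, 0, 0.05)
    vs <- variable_set(X = x, Y = y, Z = rnorm(800))
    conditional_cccm(vs, "X", "Y", "Z", E = 5, tau = 1)$ratio
  })
  expect_true(all(ratios > 0.5))

  # confounder collapse: large bivariate skill, near-zero conditional ratio
  vs <- simulate_system("confounded_trio", seed = 44)
  expect_gt(cross_map(vs$X, vs$Y, 5, 1)$rho, 0.9)
  r <- conditional_cccm(vs, "X", "Y", "Z", E = 5, tau = 1)
  expect_lt(abs(r$ratio), 0.1)
  expect_lte(r$ratio, 1)

  # a source independent of everything contributes nothing
  set.seed(45)
  null_ratios <- sapply(1:3, function(s) {
    set.seed(s + 50)
    z <- rnorm(800)
    y <- c(0, 0.8 * z[-800]) + rnorm(800, 0, 0.1)
    vs <- variable_set(S = rnorm(800), Y = y, Z = z)
    conditional_cccm(vs, "S", "Y", "Z", E = 5, tau = 1)$ratio
  })
  # an irrelevant source never shows a positive causality ratio; it can be
  # strongly negative, since a useless coordinate block dilutes the joint
  # nearest-neighbor search and inflates the error variance
  expect_true(all(null_ratios < 0.05))
})

test_that("the causality ratio is invariant to rescaling any input series", {
  vs <- simulate_system("confounded_trio", seed = 46, n = 512)
  r1 <- conditional_cccm(vs, "X", "Y", "Z", E = 4, tau = 1)$ratio
  vs2 <- variable_set(X = 1000 * vs$X, Y = vs$Y, Z = vs$Z / 1000)
  r2 <- conditional_cccm(vs2, "X", "Y", "Z", E = 4, tau = 1)$ratio
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("degenerate conditional queries are rejected", {
  vs <- simulate_system("confounded_trio", seed = 47, n = 256)
  expect_error(conditional_cccm(vs, "X", "X", "Z", 3, 1), "must differ")
  expect_error(conditional_cccm(vs, "X", "Y", character(0), 3, 1), "nonempty")
  expect_error(conditional_cccm(vs, "X", "Y", "X", 3, 1),
               "may not contain")
  # target perfectly explained without the source
  base <- rep(c(0, 1, 3, 2), 105)
  vs2 <- variable_set(A = rnorm(420), B = base, C = base)
  expect_error(conditional_cccm(vs2, "A", "B", "C", 3, 1),
               "degenerate conditioning")
})
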