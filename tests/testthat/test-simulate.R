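test_that("backcross genotypes follow the Haldane recombination model", {
  # coincident markers are perfectly linked
  map0 <- genetic_map(data.frame(marker = c("a", "b"), chr = "1",
                                 pos = c(50, 50)))
  set.seed(1)
  G <- simulate_backcross(200, map0)
  expect_identical(G[, 1], G[, 2])
  # d = 100 cM: flip frequency matches r = (1 - exp(-2))/2 within 3 SE
  map1 <- genetic_map(data.frame(marker = c("a", "b"), chr = "1",
                                 pos = c(0, 100)))
  set.seed(2)
  n <- 1e5
  G <- simulate_backcross(n, map1)
  r <- 0.5 * (1 - exp(-2))
  flips <- mean(G[, 1] != G[, 2])
  expect_lt(abs(flips - r), 3 * sqrt(r * (1 - r) / n))
  # column means near 1/2
  expect_true(all(abs(colMeans(G) - 0.5) < 3 * sqrt(0.25 / n)))
  expect_error(simulate_backcross(10, sim_map(0)))
})

test_that("genetic map validation catches malformed maps", {
  expect_error(genetic_map(data.frame(marker = c("a", "a"), chr = "1",
                                      pos = c(0, 1))), "duplicate")
  expect_error(genetic_map(data.frame(marker = c("a", "b"), chr = "1",
                                      pos = c(2, 1))), "non-decreasing")
  m <- sim_map(10, 1000)
  expect_equal(m$pos, seq(0, 1000, length.out = 10))
})

test_that("scale-free generator produces the designed edge structure", {
  set.seed(3)
  net <- simulate_scale_free(30)
  expect_equal(net$M, 29)           # 6 seed edges + 23 attachments
  expect_equal(net$n_specific, 3)   # round(0.1 * 29)
  g_common <- net$common
  expect_true(isSymmetric(g_common))
  for (At in net$conditions) {
    expect_true(all(At >= g_common))            # superset of common
    expect_equal(sum(At - g_common) / 2, 3)     # exactly 3 extra edges
  }
  # connectivity of the common graph (path seed is connected)
  reach <- diag(30)
  for (i in 1:30) reach <- pmin(reach + reach %*% g_common, 1)
  expect_true(all(reach == 1))
})

test_that("scale-free degrees are heavier-tailed than Erdos-Renyi", {
  set.seed(4)
  wins <- replicate(60, {
    ba <- max(rowSums(simulate_scale_free(30)$common))
    # ER graph with the same number of nodes and edges
    A <- matrix(0, 30, 30)
    A[sample(which(upper.tri(A)), 29)] <- 1
    er <- max(rowSums(A + t(A)))
    ba > er
  })
  expect_gt(mean(wins), 0.5)
})

test_that("row-normalized precisions are PD with support equal to the graph", {
  set.seed(5)
  for (k in 1:10) {
    net <- simulate_scale_free(30)
    A <- net$conditions[[1]]
    O <- build_precision(A)
    expect_true(isSymmetric(O))
    expect_equal(unname(diag(O)), rep(1, 30))
    expect_gt(min(eigen(O, symmetric = TRUE, only.values = TRUE)$values),
              1e-8)
    expect_identical(unname((abs(O) > 0) - diag(30) > 0), A == 1)
  }
})

test_that("dominant construction rejects structurally singular graphs", {
  # a single edge with equality diagonal dominance is always singular:
  # the rejection loop must exhaust and error
  A2 <- matrix(c(0, 1, 1, 0), 2)
  set.seed(6)
  expect_error(build_precision(A2, method = "dominant", max_tries = 25),
               "positive definite")
  # a triangle has a cycle: generically accepted, Gershgorin nonnegative
  A3 <- matrix(1, 3, 3) - diag(3)
  O <- build_precision(A3, method = "dominant")
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8)
  expect_equal(unname(diag(O)), unname(rowSums(abs(O)) - diag(O)))
  # isolated node keeps a unit diagonal instead of a singular zero
  A4 <- matrix(0, 4, 4)
  A4[1:3, 1:3] <- A3
  O4 <- build_precision(A4, method = "dominant")
  expect_equal(O4[4, 4], 1)
  expect_error(build_precision(diag(0, 3)), "no edges")
})

test_that("expression simulator reproduces the model moments", {
  set.seed(7)
  # B = 0: sample covariance approaches Omega^{-1}
  O <- matrix(c(2, -0.8, -0.8, 1), 2)
  Y <- simulate_expression(matrix(0, 1e5, 1), matrix(0, 2, 1), O)
  S <- crossprod(scale(Y, scale = FALSE)) / nrow(Y)
  expect_lt(norm(S - solve(O), "F") / norm(solve(O), "F"), 0.02)
  # Omega = I: uncorrelated unit-variance columns
  Y2 <- simulate_expression(matrix(0, 2e4, 1), matrix(0, 3, 1), diag(3))
  S2 <- crossprod(scale(Y2, scale = FALSE)) / nrow(Y2)
  expect_lt(max(abs(S2 - diag(3))), 0.05)
  # marker effects shift the mean: Y = X B' + E
  X <- matrix(c(0, 1), 100, 2)
  B <- matrix(c(1, -2), 1, 2)
  set.seed(8); Ya <- simulate_expression(X, B, diag(1))
  set.seed(8); Yb <- simulate_expression(X * 0, B, diag(1))
  expect_equal(Ya - Yb, X %*% t(B))
  expect_error(simulate_expression(X, B, matrix(-1, 1, 1)),
               "positive definite")
})

test_that("case-1 coefficients are the three fixed marker effects", {
  B <- make_case1_B()
  expect_length(B, 3)
  vals <- list(c(-0.09, 0.789, -0.667), c(1.361, 1.508, -2.608),
               c(0.687, 0.316, 2.020))
  pos <- cbind(c(1, 2, 3), c(1, 4, 8))
  for (t in 1:3) {
    expect_equal(sum(B[[t]] != 0), 3)
    expect_equal(unname(B[[t]][pos]), vals[[t]])
  }
  # deterministic: two calls agree exactly
  expect_identical(make_case1_B(), B)
})

test_that("case-2 hotspots drive gene blocks with perturbed coefficients", {
  set.seed(9)
  B <- make_case2_B()
  for (t in 1:3) expect_equal(sum(B[[t]] != 0), 30)
  # genes 19..25 load on marker 4 only
  expect_true(all(B[[1]][19:25, 4] != 0))
  expect_true(all(B[[1]][19:25, -4] == 0))
  # block-1 mean in condition 2 near 1.361 (sd 0.1, 18 genes)
  m <- mean(replicate(30, mean(make_case2_B()[[2]][1:18, 1])))
  expect_lt(abs(m - 1.361), 3 * 0.1 / sqrt(18 * 30))
})

test_that("scenario streams are deterministic and carry consistent truth", {
  r1 <- run_scenario("case2", n = 30, n_reps = 2, seed = 99)
  r2 <- run_scenario("case2", n = 30, n_reps = 2, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]]$X, r1[[2]]$X))
  for (rp in r1) {
    expect_equal(dim(rp$X), c(30, 10))
    for (t in 1:3) {
      A <- rp$adjacencies[[t]]
      expect_equal(sum(A - rp$common_adj) / 2, 3)
      O <- rp$omegas[[t]]
      expect_identical(unname((abs(O) > 0) - diag(30) > 0), A == 1)
    }
  }
})
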