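test_that("truncated-log penalty evaluates its closed form", {
  eps <- 1e-3
  # boundary: every off-diagonal pair at a = eps contributes exactly 1
  A <- matrix(eps, 3, 3); diag(A) <- 0
  expect_equal(truncated_log_penalty(A, eps), 6)
  # all-zero sums
  expect_equal(truncated_log_penalty(matrix(0, 3, 3), eps), 0)
  # single symmetric pair at a = e * eps: log branch gives 2 per ordered pair
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- exp(1) * eps
  expect_equal(truncated_log_penalty(A, eps), 4, tolerance = 1e-12)
  expect_error(truncated_log_penalty(matrix(-1, 2, 2)), "nonnegative")
})

test_that("truncated-log penalty is continuous at the truncation point", {
  eps <- 1e-3
  pen_at <- function(a) {
    A <- matrix(0, 2, 2)
    A[1, 2] <- A[2, 1] <- a
    truncated_log_penalty(A, eps)
  }
  h <- eps * 1e-12
  expect_equal(pen_at(eps), 2, tolerance = .Machine$double.eps)
  expect_lt(abs(pen_at(eps + h) - pen_at(eps - h)), 1e-9)
})

test_that("LLA weights are the reciprocal capped magnitude sums", {
  eps <- 1e-3
  O0 <- matrix(0, 3, 3)
  Z <- lla_weights(list(O0), eps)
  expect_equal(Z[1, 2], 1000)
  expect_equal(diag(Z), rep(0, 3))
  # T = 3 with omega values (0.5, -0.5, 1) for one pair
  oms <- lapply(c(0.5, -0.5, 1), function(v) {
    O <- diag(3); O[1, 2] <- O[2, 1] <- v; O
  })
  expect_equal(lla_weights(oms, eps)[1, 2], 0.5)
  # sum of 2 -> weight 1/2
  oms2 <- list(diag(3) + 1, diag(3) + 1)
  expect_equal(lla_weights(oms2, eps)[1, 3], 1 / 2)
})

test_that("initializer ridges ill-conditioned covariances until usable", {
  # identity needs no ridge
  expect_equal(initialize_omegas(list(diag(3)))[[1]], diag(3))
  # diag(1, 1e-9): ridge repeats until the eigenvalue ratio passes
  S <- diag(c(1, 1e-9))
  O <- initialize_omegas(list(S), delta_ridge = 1e-3, cond_threshold = 1e3)[[1]]
  k <- 0
  repeat {
    k <- k + 1
    ev <- c(1, 1e-9) + k * 1e-3
    if (max(ev) / min(ev) <= 1e3) break
  }
  expect_equal(O, diag(1 / (c(1, 1e-9) + k * 1e-3)), tolerance = 1e-10)
  # singular rank-1 input: output must be positive definite
  v <- c(1, 2, 3)
  O2 <- initialize_omegas(list(tcrossprod(v)))[[1]]
  expect_gt(min(eigen(O2, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("vanishing penalty recovers the inverse conditional covariance", {
  set.seed(31)
  S <- crossprod(matrix(rnorm(200 * 5), 200, 5)) / 200
  fit <- fit_jcggm(list(S), 100, lam = 1e-8)
  expect_lt(max(abs(fit$omegas[[1]] - solve(S))), 1e-4)
})

test_that("identical conditions give identical estimates at every iteration", {
  set.seed(32)
  S <- crossprod(matrix(rnorm(100 * 6), 100, 6)) / 100
  fit <- fit_jcggm(list(S, S), c(50, 50), lam = 2)
  expect_identical(fit$omegas[[1]], fit$omegas[[2]])
})

test_that("penalized profiled likelihood is non-increasing across LLA iterations", {
  set.seed(33)
  for (k in 1:4) {
    p <- 8
    S1 <- crossprod(matrix(rnorm(60 * p), 60, p)) / 60
    S2 <- crossprod(matrix(rnorm(60 * p), 60, p)) / 60
    fit <- fit_jcggm(list(S1, S2), c(60, 60), lam = runif(1, 0.5, 5))
    expect_true(all(diff(fit$objective_path) <= 1e-6 * abs(fit$objective_path[1])))
  }
})

test_that("a huge truncation point reduces the fit to one-shot scalar glasso", {
  set.seed(34)
  S <- crossprod(matrix(rnorm(80 * 5), 80, 5)) / 80
  eps_big <- 1e6  # above any reachable magnitude sum: weights constant 1/eps
  lam <- 20 * eps_big * 0.3
  fit <- fit_jcggm(list(S), 20, lam = lam, epsilon = eps_big)
  W1 <- matrix(1, 5, 5); diag(W1) <- 0
  ref <- solve_wglasso(S, W1, lam = lam / (20 * eps_big), tol = 1e-8)
  expect_lt(max(abs(fit$omegas[[1]] - ref)), 1e-4)
})

test_that("joint coupling lets a shared edge survive where an isolated one dies", {
  # two conditions, p = 4: pair (1,2) dependent in both conditions, pair
  # (3,4) equally dependent in condition 1 only; exact covariances as input
  Oc <- diag(4); Oc[1, 2] <- Oc[2, 1] <- -0.4
  O1 <- Oc; O1[3, 4] <- O1[4, 3] <- -0.4
  S1 <- solve(O1)
  S2 <- solve(Oc)
  n_ts <- c(100, 100)
  grid <- default_lambda_grid(list(S1, S2), n_ts, n_lambda = 40)
  found <- FALSE
  for (lam in grid) {
    fit <- fit_jcggm(list(S1, S2), n_ts, lam = lam)
    shared <- abs(fit$omegas[[1]][1, 2]) > 1e-6
    isolated <- abs(fit$omegas[[1]][3, 4]) > 1e-6
    if (shared && !isolated) found <- TRUE
  }
  expect_true(found)
})

test_that("BIC score matches its definition on a hand-checkable fit", {
  # Omega = Sigma^{-1} = I_3, T = 1, n = 30: logdet = 0, tr = 3, df = 3
  expect_equal(bic_score(list(diag(3)), list(diag(3)), 30),
               3 + 3 * log(30) / 30)
  # diagonal-only estimate has df = p; doubling n shrinks the df term
  b30 <- bic_score(list(diag(4)), list(diag(4)), 30)
  b60 <- bic_score(list(diag(4)), list(diag(4)), 60)
  expect_lt(b60, b30)
  expect_error(bic_score(list(-diag(3)), list(diag(3)), 30), "positive definite")
})

test_that("lambda selection returns a full BIC path and honors one-point grids", {
  set.seed(36)
  S <- crossprod(matrix(rnorm(100 * 5), 100, 5)) / 100
  one <- select_lambda(list(S), 100, lam_grid = 0.5)
  expect_equal(one$lam, 0.5)
  grid <- default_lambda_grid(list(S), 100, n_lambda = 8)
  sel <- select_lambda(list(S), 100, lam_grid = grid)
  expect_length(sel$bic_path, 8)
  expect_equal(sel$lam, grid[which.min(sel$bic_path)])
})

test_that("support recovery improves with sample size", {
  reps <- 8
  fit_one <- function(n, seed) {
    rp <- run_scenario("case1", n = n, n_reps = 1, seed = seed)[[1]]
    sig <- suppressWarnings(lapply(rp$Y, function(Y) linear_cond_cov(Y, rp$X)))
    sel <- select_lambda(sig, rep(n, 3), lam_grid =
      default_lambda_grid(sig, rep(n, 3), n_lambda = 15))
    m <- fp_fn_rates(sel$fit, rp$adjacencies)
    m[["fp"]] + m[["fn"]]
  }
  err30 <- sapply(seq_len(reps), function(s) fit_one(30, 500 + s))
  err100 <- sapply(seq_len(reps), function(s) fit_one(100, 500 + s))
  expect_lt(median(err100), median(err30))
})
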