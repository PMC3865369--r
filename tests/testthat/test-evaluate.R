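edge_mat <- function(p, edges) {
  A <- matrix(0, p, p)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}
prec_from_adj <- function(A, v = 0.5) {
  O <- A * -v
  diag(O) <- 1
  O
}

test_that("FP/FN rates follow the per-condition edge-count definitions", {
  truth <- list(edge_mat(3, list(c(1, 2))))
  est <- list(prec_from_adj(edge_mat(3, list(c(1, 3)))))
  r <- fp_fn_rates(est, truth)
  expect_equal(unname(r["fp"]), 1 / 2)   # 2 true zeros, one estimated edge
  expect_equal(unname(r["fn"]), 1)       # single true edge missed
  # perfect recovery and empty estimate
  est2 <- list(prec_from_adj(truth[[1]]))
  expect_equal(unname(fp_fn_rates(est2, truth)), c(0, 0))
  est3 <- list(diag(3))
  expect_equal(unname(fp_fn_rates(est3, truth)), c(0, 1))
})

test_that("rate denominators of zero raise informative errors", {
  full <- list(edge_mat(2, list(c(1, 2))))
  expect_error(fp_fn_rates(list(diag(2)), full), "no true zeros")
  empty <- list(matrix(0, 3, 3))
  expect_error(fp_fn_rates(list(diag(3)), empty), "no true edges")
  expect_error(common_zero_rates(list(diag(2)), full), "no common zeros")
})

test_that("common-zero rates enumerate the joint pattern", {
  # T=2, p=3: truth edges cond1 {(1,2)}, cond2 none;
  # estimates: cond1 none, cond2 {(1,3)}
  truth <- list(edge_mat(3, list(c(1, 2))), matrix(0, 3, 3))
  est <- list(diag(3), prec_from_adj(edge_mat(3, list(c(1, 3)))))
  r <- common_zero_rates(est, truth)
  expect_equal(unname(r["fpc"]), 1 / 2)  # common zeros {(1,3),(2,3)}, one hit
  expect_equal(unname(r["fnc"]), 1)      # union edge (1,2) missed everywhere
  # complete-graph estimates: all common zeros violated, nothing missed
  full <- lapply(1:2, function(i) prec_from_adj(matrix(1, 3, 3) - diag(3), 0.3))
  r2 <- common_zero_rates(full, truth)
  expect_equal(unname(r2), c(1, 0))
})

test_that("relative Frobenius loss matches hand computations", {
  expect_equal(relative_frobenius_loss(list(diag(2)), list(diag(2))), 0)
  expect_equal(relative_frobenius_loss(list(matrix(0, 2, 2)), list(diag(2))), 1)
  expect_equal(relative_frobenius_loss(list(2 * diag(2)), list(diag(2))), 1)
})

test_that("all rates are invariant under simultaneous gene relabeling", {
  set.seed(21)
  rp <- run_scenario("case1", n = 50, n_reps = 1, seed = 77)[[1]]
  est <- lapply(rp$omegas, function(O) {
    O[abs(O) < 0.05] <- 0  # degrade the truth into an imperfect estimate
    O
  })
  m1 <- metric_report(est, rp$adjacencies, rp$omegas)
  perm <- sample(30)
  m2 <- metric_report(
    lapply(est, function(O) O[perm, perm]),
    lapply(rp$adjacencies, function(A) A[perm, perm]),
    lapply(rp$omegas, function(O) O[perm, perm])
  )
  expect_equal(m1, m2)
})

test_that("ROC path runs from the empty corner toward the dense corner", {
  set.seed(22)
  rp <- run_scenario("case1", n = 100, n_reps = 1, seed = 5)[[1]]
  sig <- suppressWarnings(lapply(rp$Y, function(Y) linear_cond_cov(Y, rp$X)))
  roc <- roc_path(sig, rep(100, 3), rp$adjacencies,
                  lam_grid = default_lambda_grid(sig, rep(100, 3),
                                                 n_lambda = 12, ratio = 1e6))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_gt(roc$tpr[nrow(roc)], 0.8)
  expect_gt(roc$fpr[nrow(roc)], 0.5)
  # sorted by FPR, and TPR mostly non-decreasing along the path
  expect_true(!is.unsorted(roc$fpr))
  dt <- diff(roc$tpr)
  expect_gte(mean(dt >= -1e-9), 0.95)
  expect_error(roc_path(sig, rep(100, 3), rp$adjacencies, lam_grid = numeric(0)),
               "empty")
})

test_that("benchmark summary reports means with standard errors", {
  bench <- data.frame(
    rep = rep(1:3, 2), method = rep(c("A", "B"), each = 3),
    fp = c(0.1, 0.2, 0.3, 0, 0, 0), fn = 0.5, fpc = 0.1, fnc = 0.2,
    rfl = c(1, 1, 1, 2, 2, 2)
  )
  s <- summarize_benchmark(bench)
  expect_equal(s$fp_mean[s$method == "A"], 0.2)
  expect_equal(s$fp_se[s$method == "A"], sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(s$rfl_se[s$method == "B"], 0)
})
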