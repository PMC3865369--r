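# Independent reference solver for the weighted graphical lasso, used as a
# brute-force oracle: ADMM with an eigendecomposition-based likelihood
# proximal step and element-wise soft-thresholding. Shares no code path with
# the package's block-coordinate-descent solver.
admm_wglasso <- function(S, W, lam, rho = 1, max_iter = 5000, tol = 1e-10) {
  p <- nrow(S)
  R <- lam * W
  diag(R) <- 0
  Z <- diag(1 / diag(S), p)
  U <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(max_iter)) {
    # Omega-step: argmin tr(S O) - logdet O + (rho/2)||O - Z + U||_F^2
    e <- eigen((rho * (Z - U) - S) / rho, symmetric = TRUE)
    ev <- (e$values + sqrt(e$values^2 + 4 / rho)) / 2
    Omega <- e$vectors %*% (ev * t(e$vectors))
    Zold <- Z
    Z <- soft(Omega + U, R / rho)
    diag(Z) <- diag(Omega + U)
    U <- U + Omega - Z
    pri <- max(abs(Omega - Z))
    dua <- max(abs(rho * (Z - Zold)))
    if (pri < tol && dua < tol) break
  }
  Z
}

wg_objective <- function(S, W, lam, Omega) {
  Wz <- W
  diag(Wz) <- 0
  sum(S * Omega) - as.numeric(determinant(Omega, TRUE)$modulus) +
    lam * sum(Wz * abs(Omega))
}

# random symmetric PD-ish covariance and nonnegative symmetric weights
rand_wglasso_instance <- function(p, n = 3 * p) {
  Y <- matrix(rnorm(n * p), n, p)
  S <- crossprod(Y) / n
  W <- matrix(runif(p * p, 0.2, 2), p, p)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  lam <- runif(1, 0.05, 0.5)
  list(S = S, W = W, lam = lam)
}
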