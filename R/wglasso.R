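#' Solve a weighted graphical lasso problem
#'
#' Minimizes \deqn{\mathrm{tr}(S\Omega) - \log\det\Omega +
#' \lambda \sum_{j\neq k} W_{jk} |\omega_{jk}|} over symmetric positive
#' definite matrices, with element-wise off-diagonal penalty weights
#' \code{W} and an unpenalized diagonal. This is the inner subproblem of the
#' LLA iteration in \code{\link{fit_jcggm}}; with \code{W} all ones it is the
#' ordinary graphical lasso.
#'
#' The solver is a primal block-coordinate descent on the columns of
#' \eqn{\Omega}; each column update is an l1-penalized quadratic program
#' solved by coordinate descent, so the iterate remains positive definite
#' throughout and the objective decreases at every sweep.
#'
#' @param S symmetric input covariance matrix with strictly positive
#'   diagonal (it need not be positive definite; a singular \code{S} is
#'   admissible when \code{lam > 0} and all off-diagonal weights are
#'   positive, though the solution can then be very large in norm).
#' @param W symmetric nonnegative weight matrix with zero diagonal;
#'   default all ones off the diagonal (scalar-penalty graphical lasso).
#' @param lam nonnegative penalty level \eqn{\lambda}.
#' @param Omega0 optional positive definite warm start; default
#'   \code{diag(1/(diag(S) + lam))}.
#' @param tol convergence tolerance: the sweep stops when the mean absolute
#'   change of the entries of \eqn{\Omega} drops below
#'   \code{tol * mean(|off-diagonal of S|)}.
#' @param max_iter maximum number of block-coordinate sweeps.
#' @param on_nonconvergence what to do when \code{max_iter} is reached
#'   without meeting \code{tol}: raise an error (carrying the last iterate
#'   in the condition's \code{data}), warn, or stay silent. In all cases
#'   the last iterate is returned.
#'
#' @return The estimated precision matrix (symmetric positive definite),
#'   with attributes \code{converged}, \code{iters}, \code{delta} (last
#'   sweep's mean absolute change) and \code{obj_path} (objective value
#'   after each sweep, non-increasing).
#' @seealso \code{\link{kkt_residual}} for an optimality certificate.
#' @export
solve_wglasso <- function(S, W = NULL, lam, Omega0 = NULL, tol = 1e-5,
                          max_iter = 500,
                          on_nonconvergence = c("warning", "error", "silent")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  S <- as.matrix(S)
  p <- nrow(S)
  stopifnot(ncol(S) == p, lam >= 0, is.finite(lam))
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("S must be symmetric")
  }
  S <- (S + t(S)) / 2
  if (any(diag(S) < 0)) {
    stop("S has a negative diagonal entry (not a covariance matrix)")
  }
  if (any(diag(S) <= 0)) {
    stop("S has a zero diagonal entry; the unpenalized-diagonal problem is unbounded")
  }
  if (is.null(W)) {
    W <- matrix(1, p, p)
    diag(W) <- 0
  }
  W <- as.matrix(W)
  stopifnot(dim(W) == c(p, p))
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) {
    stop("W must be symmetric")
  }
  if (any(W < 0)) stop("W must be nonnegative")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (is.null(Omega0)) {
    Omega0 <- diag(1 / (diag(S) + lam), p)
  }

  fit <- .wglasso_cpp(S, W, lam, Omega0, tol, as.integer(max_iter))
  Omega <- (fit$Omega + t(fit$Omega)) / 2
  if (!fit$converged) {
    msg <- sprintf(
      "weighted glasso did not reach tol within %d sweeps (last mean change %.3g)",
      max_iter, fit$delta
    )
    if (on_nonconvergence == "error") {
      cond <- simpleError(msg)
      cond$data <- list(Omega = Omega, delta = fit$delta)
      stop(cond)
    } else if (on_nonconvergence == "warning") {
      warning(msg)
    }
  }
  attr(Omega, "converged") <- fit$converged
  attr(Omega, "iters") <- fit$iters
  attr(Omega, "delta") <- fit$delta
  attr(Omega, "obj_path") <- fit$obj_path
  Omega
}

#' Objective value of the weighted graphical lasso problem
#'
#' @inheritParams solve_wglasso
#' @param Omega positive definite matrix at which to evaluate.
#' @return \code{tr(S Omega) - logdet(Omega) + lam * sum(W * |Omega|)}.
#' @export
wglasso_objective <- function(S, W, lam, Omega) {
  W <- as.matrix(W)
  diag(W) <- 0
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("Omega is not positive definite")
  sum(S * Omega) - as.numeric(ld$modulus) + lam * sum(W * abs(Omega))
}

#' KKT residual of a candidate weighted-glasso solution
#'
#' Measures the worst-case violation of the stationarity conditions of the
#' objective solved by \code{\link{solve_wglasso}}. For a nonzero
#' off-diagonal entry the condition is
#' \eqn{S_{jk} - (\Omega^{-1})_{jk} + \lambda W_{jk}\,\mathrm{sign}(\omega_{jk}) = 0};
#' for a zero entry the subgradient may lie anywhere in
#' \eqn{[-\lambda W_{jk}, \lambda W_{jk}]}; the diagonal (unpenalized) must
#' satisfy \eqn{S_{jj} = (\Omega^{-1})_{jj}}.
#'
#' @inheritParams wglasso_objective
#' @return the maximum entry-wise violation (nonnegative scalar).
#' @export
kkt_residual <- function(S, W, lam, Omega) {
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("Omega must be positive definite (invertible)")
  W <- as.matrix(W)
  diag(W) <- 0
  D <- S - solve(Omega)
  nz <- Omega != 0
  diag(nz) <- FALSE
  res_nz <- abs(D + lam * W * sign(Omega))
  res_z <- pmax(0, abs(D) - lam * W)
  R <- ifelse(nz, res_nz, res_z)
  diag(R) <- abs(diag(D))
  max(R)
}
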