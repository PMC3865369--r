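#' Truncated-log joint sparsity penalty
#'
#' Evaluates \eqn{\sum_{j \neq j'} g(a_{jj'})} over ordered off-diagonal
#' pairs, where \eqn{a_{jj'} = \sum_t |\omega^{(t)}_{jj'}|} and
#' \deqn{g(a) = \log a - \log\epsilon + 1 \quad (a > \epsilon), \qquad
#'       g(a) = a/\epsilon \quad (a \le \epsilon).}
#' The two branches meet at \eqn{a = \epsilon} with value 1, so the penalty
#' is continuous and concave; its derivative \eqn{1/\max(a, \epsilon)} is the
#' LLA weight of \code{\link{lla_weights}}. Below \eqn{\epsilon} the penalty
#' behaves like a lasso with level \eqn{1/\epsilon}; above it grows only
#' logarithmically, so an edge that is well supported in any condition is
#' cheap to strengthen in all of them — this is what couples the conditions.
#'
#' @param omega_sums symmetric nonnegative matrix of per-pair sums
#'   \eqn{\sum_t |\omega^{(t)}_{jj'}|}; the diagonal is ignored.
#' @param epsilon truncation point (> 0), default \code{1e-3}.
#' @return the scalar penalty value (both ordered pairs of each edge count,
#'   matching the \eqn{\sum_{j\neq j'}} convention).
#' @export
truncated_log_penalty <- function(omega_sums, epsilon = 1e-3) {
  A <- as.matrix(omega_sums)
  stopifnot(epsilon > 0)
  if (any(A < 0)) stop("omega_sums must be nonnegative")
  a <- A[row(A) != col(A)]
  sum(ifelse(a > epsilon, log(a) - log(epsilon) + 1, a / epsilon))
}

#' LLA weights from the previous joint estimate
#'
#' The local linear approximation replaces the concave truncated-log penalty
#' by its tangent at the current iterate, giving per-pair lasso weights
#' \deqn{\zeta_{jj'} = 1 / \max\left(\sum_t |\omega^{(t)}_{jj'}|, \epsilon\right).}
#' Pairs with no current support get the maximal weight \eqn{1/\epsilon};
#' the diagonal is unpenalized (weight 0).
#'
#' @param omegas list of T symmetric precision matrices (previous iterate).
#' @param epsilon truncation point of the penalty.
#' @return symmetric nonnegative weight matrix with zero diagonal.
#' @export
lla_weights <- function(omegas, epsilon = 1e-3) {
  stopifnot(epsilon > 0, length(omegas) >= 1)
  A <- Reduce(`+`, lapply(omegas, abs))
  Z <- 1 / pmax(A, epsilon)
  diag(Z) <- 0
  Z
}

#' Initial precision estimates from (possibly ill-conditioned) covariances
#'
#' Returns \eqn{(\hat\Sigma^{(t)} + k\delta I_p)^{-1}} where the ridge
#' \eqn{\delta} is added to the diagonal repeatedly (k = 0, 1, 2, ...) until
#' the eigenvalue condition number drops to \code{cond_threshold} or below
#' (a nonpositive smallest eigenvalue always triggers the ridge). This keeps
#' the initializer finite for the singular conditional covariances that
#' arise when the sample size is small relative to the covariate count.
#'
#' @param sigmas list of T symmetric covariance estimates.
#' @param delta_ridge ridge increment added per round (default 1e-3).
#' @param cond_threshold maximal allowed eigenvalue ratio (default 1e3).
#' @return list of T symmetric positive definite matrices.
#' @export
initialize_omegas <- function(sigmas, delta_ridge = 1e-3, cond_threshold = 1e3) {
  lapply(sigmas, function(S) {
    S <- (S + t(S)) / 2
    p <- nrow(S)
    repeat {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0 && max(ev) / min(ev) <= cond_threshold) break
      S <- S + diag(delta_ridge, p)
    }
    O <- chol2inv(chol(S))
    (O + t(O)) / 2
  })
}

#' Default lambda grid for the joint fit
#'
#' Log-spaced descending grid of \code{n_lambda} values from
#' \eqn{\lambda_{max}} down to \eqn{\lambda_{max}/ratio}.
#' \eqn{\lambda_{max}} is the soft-threshold bound that zeroes every edge
#' at the first LLA iteration given the actual initializer: with initial
#' weights \eqn{\zeta_{jj'} = 1/\max(a_{jj'}, \epsilon)}, where
#' \eqn{a_{jj'} = \sum_t |\omega^{(t)}_{0,jj'}|} from
#' \code{\link{initialize_omegas}}, the pair \eqn{(j,j')} of condition t is
#' zeroed whenever \eqn{\lambda \zeta_{jj'}/n_t \ge |\hat\Sigma^{(t)}_{jj'}|},
#' so \deqn{\lambda_{max} = \max_{t}\; n_t \max_{j\neq j'}
#'   |\hat\Sigma^{(t)}_{jj'}| \max(a_{jj'}, \epsilon).}
#' At that level the fit is the empty graph and stays empty in subsequent
#' iterations (the released weights rise to the cap \eqn{1/\epsilon}); the
#' bottom of the grid approaches the dense fit, so the warm-started
#' descending path spans the whole sparsity range.
#'
#' @param sigmas list of T covariance estimates.
#' @param n_ts integer vector of per-condition sample sizes.
#' @param epsilon penalty truncation point.
#' @param n_lambda grid size (default 30).
#' @param ratio \eqn{\lambda_{max}/\lambda_{min}} (default 1e5).
#' @param omegas0 optional initial precisions; default
#'   \code{\link{initialize_omegas}(sigmas)}.
#' @return numeric vector, strictly positive, sorted descending.
#' @export
default_lambda_grid <- function(sigmas, n_ts, epsilon = 1e-3,
                                n_lambda = 30, ratio = 1e5,
                                omegas0 = NULL) {
  if (is.null(omegas0)) omegas0 <- initialize_omegas(sigmas)
  A <- Reduce(`+`, lapply(omegas0, abs))
  lam_max <- max(vapply(seq_along(sigmas), function(t) {
    B <- abs(sigmas[[t]]) * pmax(A, epsilon)
    n_ts[t] * max(B[row(B) != col(B)])
  }, numeric(1)))
  if (lam_max <= 0) lam_max <- epsilon
  exp(seq(log(lam_max), log(lam_max / ratio), length.out = n_lambda))
}

#' Fit the joint conditional Gaussian graphical model at one lambda
#'
#' Minimizes the penalized profiled likelihood
#' \deqn{\sum_t n_t\left(-\log\det\Omega^{(t)} +
#'   \mathrm{tr}(\hat\Sigma^{(t)}\Omega^{(t)})\right) +
#'   \lambda P(\{\Omega^{(t)}\})}
#' with the truncated-log joint penalty \eqn{P}, by local linear
#' approximation: at each iteration the penalty is replaced by its tangent,
#' and each condition is solved as a weighted graphical lasso
#' \code{\link{solve_wglasso}} with weights \code{\link{lla_weights}} and
#' level \eqn{\lambda/n_t} (the subproblem is normalized by \eqn{n_t}, which
#' is the same problem after dividing through by the sample size). Because
#' the penalty is concave in the \eqn{\sum_t|\omega|} sums, each LLA step is
#' a majorize-minimize step and the objective path is non-increasing.
#'
#' @param sigmas list of T p x p conditional covariance estimates.
#' @param n_ts integer vector of T sample sizes.
#' @param lam penalty level \eqn{\lambda > 0}.
#' @param epsilon truncation point of the penalty (default 1e-3).
#' @param omegas0 optional list of T warm-start precisions; default
#'   \code{\link{initialize_omegas}}.
#' @param lla_tol stop when the largest relative Frobenius change across
#'   conditions falls below this (default 1e-4).
#' @param lla_max_iter maximal LLA iterations (default 50).
#' @param wg_tol,wg_max_iter tolerance and sweep cap of the inner solver.
#' @param delta_ridge,cond_threshold passed to \code{\link{initialize_omegas}}.
#' @param on_nonconvergence inner-solver behaviour, see
#'   \code{\link{solve_wglasso}}.
#' @return object of class \code{"jcggm_fit"}: list with \code{omegas}
#'   (list of T precision matrices), \code{lam}, \code{epsilon},
#'   \code{n_iters}, \code{converged}, and \code{objective_path} (penalized
#'   profiled likelihood after each accepted iteration, non-increasing).
#' @export
fit_jcggm <- function(sigmas, n_ts, lam, epsilon = 1e-3, omegas0 = NULL,
                      lla_tol = 1e-4, lla_max_iter = 50,
                      wg_tol = 1e-5, wg_max_iter = 500,
                      delta_ridge = 1e-3, cond_threshold = 1e3,
                      on_nonconvergence = "silent") {
  T_ <- length(sigmas)
  stopifnot(T_ >= 1, length(n_ts) == T_, lam > 0, epsilon > 0)
  sigmas <- lapply(sigmas, function(S) (as.matrix(S) + t(as.matrix(S))) / 2)
  p <- nrow(sigmas[[1]])
  stopifnot(all(vapply(sigmas, nrow, 1L) == p))

  omegas <- if (is.null(omegas0)) {
    initialize_omegas(sigmas, delta_ridge, cond_threshold)
  } else {
    omegas0
  }

  ppl <- function(oms) {
    lik <- sum(vapply(seq_len(T_), function(t) {
      ld <- determinant(oms[[t]], logarithm = TRUE)
      if (ld$sign <= 0) return(Inf)
      n_ts[t] * (sum(sigmas[[t]] * oms[[t]]) - as.numeric(ld$modulus))
    }, numeric(1)))
    A <- Reduce(`+`, lapply(oms, abs))
    lik + lam * truncated_log_penalty(A, epsilon)
  }

  obj_path <- ppl(omegas)
  converged <- FALSE
  k <- 0
  while (k < lla_max_iter) {
    k <- k + 1
    Z <- lla_weights(omegas, epsilon)
    new_omegas <- vector("list", T_)
    for (t in seq_len(T_)) {
      new_omegas[[t]] <- solve_wglasso(
        sigmas[[t]], W = Z, lam = lam / n_ts[t],
        Omega0 = omegas[[t]], tol = wg_tol, max_iter = wg_max_iter,
        on_nonconvergence = on_nonconvergence
      )
    }
    rel <- max(vapply(seq_len(T_), function(t) {
      norm(new_omegas[[t]] - omegas[[t]], "F") /
        max(norm(omegas[[t]], "F"), .Machine$double.eps)
    }, numeric(1)))
    omegas <- new_omegas
    obj_path <- c(obj_path, ppl(omegas))
    if (rel < lla_tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      omegas = omegas, lam = lam, epsilon = epsilon,
      n_iters = k, converged = converged, objective_path = obj_path
    ),
    class = "jcggm_fit"
  )
}

#' @export
print.jcggm_fit <- function(x, ...) {
  p <- nrow(x$omegas[[1]])
  ne <- vapply(x$omegas, function(O) sum(abs(O[upper.tri(O)]) > 1e-6), 0L)
  cat(sprintf(
    "Joint GGM fit: T = %d conditions, p = %d, lambda = %.4g\n",
    length(x$omegas), p, x$lam
  ))
  cat(sprintf(
    "  edges per condition: %s\n  LLA iterations: %d (converged: %s)\n",
    paste(ne, collapse = ", "), x$n_iters, x$converged
  ))
  invisible(x)
}

#' BIC score of a fitted precision set
#'
#' \deqn{\mathrm{BIC}(\lambda) = \sum_t\left\{-\log\det\hat\Omega^{(t)} +
#'   \mathrm{tr}(\hat\Sigma^{(t)}\hat\Omega^{(t)}) +
#'   \log(n_t)\,\mathrm{df}_t / n_t\right\}}
#' with \eqn{\mathrm{df}_t} the number of upper-triangle entries (diagonal
#' included) exceeding \code{edge_tol} in absolute value.
#'
#' @param omegas list of T precision matrices (or a \code{jcggm_fit}).
#' @param sigmas list of T covariance estimates used in the fit.
#' @param n_ts per-condition sample sizes.
#' @param edge_tol magnitude below which an entry counts as zero
#'   (default 1e-6).
#' @return the BIC value (scalar; smaller is better).
#' @export
bic_score <- function(omegas, sigmas, n_ts, edge_tol = 1e-6) {
  if (inherits(omegas, "jcggm_fit")) omegas <- omegas$omegas
  T_ <- length(omegas)
  stopifnot(length(sigmas) == T_, length(n_ts) == T_)
  sum(vapply(seq_len(T_), function(t) {
    O <- omegas[[t]]
    ld <- determinant(O, logarithm = TRUE)
    if (ld$sign <= 0) stop("precision matrix is not positive definite")
    df_t <- sum(abs(O[upper.tri(O, diag = TRUE)]) > edge_tol)
    -as.numeric(ld$modulus) + sum(sigmas[[t]] * O) +
      log(n_ts[t]) * df_t / n_ts[t]
  }, numeric(1)))
}

#' BIC-tuned joint fit over a lambda path
#'
#' Fits \code{\link{fit_jcggm}} for every value of a descending lambda grid,
#' warm-starting each fit from the previous solution, and returns the fit
#' minimizing \code{\link{bic_score}}. Ties go to the larger lambda
#' (sparser model).
#'
#' @inheritParams fit_jcggm
#' @param lam_grid descending positive grid; default
#'   \code{\link{default_lambda_grid}}.
#' @param edge_tol passed to \code{\link{bic_score}}.
#' @param bic_patience stop descending the grid once the BIC has exceeded
#'   its running minimum for this many consecutive grid points (the BIC
#'   path is empirically U-shaped in lambda, so the expensive dense tail
#'   need not be fitted once the upturn is established). Set to
#'   \code{Inf} to fit the whole grid (as \code{\link{roc_path}} does).
#' @param ... further arguments to \code{\link{fit_jcggm}}.
#' @return list with \code{lam} (selected), \code{fit} (the selected
#'   \code{jcggm_fit}), \code{lam_grid} (evaluated portion),
#'   \code{bic_path} and \code{fits} (all fits along the evaluated path).
#' @export
select_lambda <- function(sigmas, n_ts, epsilon = 1e-3, lam_grid = NULL,
                          edge_tol = 1e-6, bic_patience = 6, ...) {
  if (is.null(lam_grid)) {
    lam_grid <- default_lambda_grid(sigmas, n_ts, epsilon)
  }
  stopifnot(length(lam_grid) >= 1, all(lam_grid > 0),
            !is.unsorted(rev(lam_grid)))
  fits <- vector("list", length(lam_grid))
  bic <- rep(NA_real_, length(lam_grid))
  warm <- NULL
  n_eval <- length(lam_grid)
  for (i in seq_along(lam_grid)) {
    fits[[i]] <- fit_jcggm(sigmas, n_ts, lam = lam_grid[i],
                           epsilon = epsilon, omegas0 = warm, ...)
    warm <- fits[[i]]$omegas
    bic[i] <- bic_score(fits[[i]]$omegas, sigmas, n_ts, edge_tol)
    bmin <- min(bic[seq_len(i)])
    near <- which(bic[seq_len(i)] <= bmin + 1e-8 * max(1, abs(bmin)))
    if (i - max(near) >= bic_patience) {
      n_eval <- i
      break
    }
  }
  keep <- seq_len(n_eval)
  bic <- bic[keep]
  fits <- fits[keep]
  best <- which.min(bic)  # grid descending: first minimum = largest lambda
  list(
    lam = lam_grid[best], fit = fits[[best]],
    lam_grid = lam_grid[keep], bic_path = bic, fits = fits
  )
}

#' Separate scalar-penalty graphical lasso fits with per-condition BIC
#'
#' The per-condition baseline: each condition's precision matrix is
#' estimated on its own by an ordinary graphical lasso (all off-diagonal
#' weights 1, diagonal unpenalized) over a descending penalty grid, with the
#' penalty chosen per condition by the same BIC formula as the joint fit.
#' Applied to marginal covariances this is the unconditional GGM baseline;
#' applied to conditional covariances it is the separately-estimated
#' conditional GGM baseline.
#'
#' @param sigmas list of T covariance estimates.
#' @param n_ts per-condition sample sizes.
#' @param rho_grid descending positive grid of penalty levels on the
#'   \code{tr - logdet + rho * sum|omega|} scale; default 30 log-spaced
#'   values per condition from the full-shrinkage level
#'   \code{max |off-diagonal|} down by a factor 1000.
#' @param edge_tol BIC zero threshold.
#' @param wg_tol,wg_max_iter inner solver controls. The default sweep cap
#'   (50) bounds the effort spent on penalty levels whose subproblem has
#'   no finite minimizer, which happens for singular covariances (sample
#'   size below the dimension, or heavy covariate conditioning) at small
#'   penalties; the returned iterate is then the solver's last sweep and
#'   its entries can be very large -- the degenerate regime the
#'   small-sample conditional benchmark exhibits.
#' @param bic_patience stop a condition's path after this many consecutive
#'   grid points above the running BIC minimum; \code{Inf} disables.
#' @return list with \code{omegas} (selected per-condition precisions),
#'   \code{rho} (selected level per condition), \code{bic_paths},
#'   \code{rho_grids} and \code{fits} (per condition, per grid point).
#' @export
fit_separate_glasso <- function(sigmas, n_ts, rho_grid = NULL,
                                edge_tol = 1e-6, wg_tol = 1e-5,
                                wg_max_iter = 50, bic_patience = Inf) {
  T_ <- length(sigmas)
  omegas <- vector("list", T_)
  rhos <- numeric(T_)
  bic_paths <- vector("list", T_)
  rho_grids <- vector("list", T_)
  fits <- vector("list", T_)
  for (t in seq_len(T_)) {
    S <- (as.matrix(sigmas[[t]]) + t(as.matrix(sigmas[[t]]))) / 2
    grid <- rho_grid
    if (is.null(grid)) {
      rmax <- max(abs(S[row(S) != col(S)]))
      if (rmax <= 0) rmax <- 1e-3
      grid <- exp(seq(log(rmax), log(rmax / 1000), length.out = 30))
    }
    W1 <- matrix(1, nrow(S), ncol(S))
    diag(W1) <- 0
    warm <- NULL
    path_fits <- vector("list", length(grid))
    bic <- rep(NA_real_, length(grid))
    n_eval <- length(grid)
    for (i in seq_along(grid)) {
      O <- solve_wglasso(S, W = W1, lam = grid[i], Omega0 = warm,
                         tol = wg_tol, max_iter = wg_max_iter,
                         on_nonconvergence = "silent")
      warm <- O
      path_fits[[i]] <- O
      bic[i] <- bic_score(list(O), list(S), n_ts[t], edge_tol)
      bmin <- min(bic[seq_len(i)])
      near <- which(bic[seq_len(i)] <= bmin + 1e-8 * max(1, abs(bmin)))
      if (i - max(near) >= bic_patience) {
        n_eval <- i
        break
      }
    }
    grid <- grid[seq_len(n_eval)]
    bic <- bic[seq_len(n_eval)]
    path_fits <- path_fits[seq_len(n_eval)]
    best <- which.min(bic)
    omegas[[t]] <- path_fits[[best]]
    rhos[t] <- grid[best]
    bic_paths[[t]] <- bic
    rho_grids[[t]] <- grid
    fits[[t]] <- path_fits
  }
  list(omegas = omegas, rho = rhos, bic_paths = bic_paths,
       rho_grids = rho_grids, fits = fits)
}
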