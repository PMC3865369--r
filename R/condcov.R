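#' Gram (kernel) matrix of a covariate matrix
#'
#' @param X numeric matrix, samples in rows.
#' @param kind kernel type: \code{"linear"} (\eqn{XX^T}), \code{"rbf"}
#'   (\eqn{\exp(-\|x_i-x_j\|^2 / 2\sigma^2)}) or \code{"polynomial"}
#'   (\eqn{(x_i^T x_j + 1)^d}).
#' @param sigma RBF bandwidth (> 0). Default: median pairwise Euclidean
#'   distance between rows of \code{X} (the usual median heuristic), falling
#'   back to 1 when all rows coincide.
#' @param degree polynomial degree (integer >= 1).
#' @return n x n symmetric kernel matrix.
#' @export
make_kernel <- function(X, kind = c("linear", "rbf", "polynomial"),
                        sigma = NULL, degree = 2L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (kind == "linear") {
    K <- tcrossprod(X)
  } else if (kind == "rbf") {
    d2 <- as.matrix(stats::dist(X))^2
    if (is.null(sigma)) {
      dd <- sqrt(d2[upper.tri(d2)])
      sigma <- stats::median(dd[dd > 0])
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    if (sigma <= 0) stop("rbf bandwidth sigma must be > 0")
    K <- exp(-d2 / (2 * sigma^2))
  } else {
    if (degree < 1) stop("polynomial degree must be >= 1")
    K <- (tcrossprod(X) + 1)^degree
  }
  (K + t(K)) / 2
}

#' Conditional covariance of Y given X through a kernel
#'
#' Estimates the covariance of the gene-expression vector after the part
#' explained by the covariates has been removed, using the reproducing-kernel
#' conditional variance estimator
#' \deqn{\hat\Sigma = \frac1n\left(Y^T Q Y - Y^T Q\,(QKQ)(QKQ)^\dagger\,Q Y\right),}
#' where \eqn{Q = I_n - J_n/n} centers the samples, \eqn{K} is the covariate
#' Gram matrix and \eqn{\dagger} the Moore-Penrose pseudoinverse. The matrix
#' \eqn{(QKQ)(QKQ)^\dagger} is the orthogonal projector onto the column space
#' of the centered kernel, so with a linear kernel the estimator reduces to
#' \code{\link{linear_cond_cov}}.
#'
#' @param Y n x p expression matrix (samples in rows).
#' @param K n x n symmetric positive semidefinite kernel matrix
#'   (e.g. from \code{\link{make_kernel}}).
#' @param pinv_tol relative singular-value cutoff for the pseudoinverse.
#' @return p x p symmetric positive semidefinite matrix (divisor n).
#' @export
kernel_cond_cov <- function(Y, K, pinv_tol = 1e-10) {
  Y <- as.matrix(Y)
  K <- as.matrix(K)
  n <- nrow(Y)
  stopifnot(n >= 2, nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("K must be symmetric")
  }
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("K has a substantially negative eigenvalue; not a valid kernel matrix")
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)         # Q Y
  Kc <- scale(t(scale(t(K), center = TRUE, scale = FALSE)),
              center = TRUE, scale = FALSE)            # Q K Q
  Kc <- (Kc + t(Kc)) / 2
  # projector onto col(QKQ) via eigendecomposition
  e <- eigen(Kc, symmetric = TRUE)
  keep <- abs(e$values) > pinv_tol * max(abs(e$values), .Machine$double.eps)
  if (any(keep)) {
    U <- e$vectors[, keep, drop = FALSE]
    PY <- U %*% crossprod(U, Yc)                       # projection of QY
  } else {
    PY <- matrix(0, n, ncol(Y))
  }
  S <- (crossprod(Yc) - crossprod(Yc, PY)) / n
  (S + t(S)) / 2
}

#' Conditional covariance of Y given X with a linear kernel
#'
#' The closed form \eqn{S_{YY} - S_{YX} S_{XX}^\dagger S_{XY}} with all
#' moment matrices computed from mean-centered \code{Y} and \code{X} and
#' divisor n. With \code{q = 0} columns (or \code{X = NULL}) this is the
#' plain centered sample covariance, so the unconditional Gaussian graphical
#' model is the degenerate case of the pipeline.
#'
#' Rank deficiency of \eqn{S_{XX}} is handled by the pseudoinverse. When
#' \code{n <= q} the estimate is typically singular (the covariates can
#' interpolate the data); a warning is emitted.
#'
#' @param Y n x p expression matrix.
#' @param X n x q covariate matrix, or NULL for the unconditional case.
#' @param pinv_tol relative singular-value cutoff for the pseudoinverse.
#' @return p x p symmetric positive semidefinite matrix.
#' @export
linear_cond_cov <- function(Y, X = NULL, pinv_tol = 1e-10) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(n >= 2)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  S_YY <- crossprod(Yc) / n
  if (is.null(X) || NCOL(X) == 0) {
    return((S_YY + t(S_YY)) / 2)
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  q <- ncol(X)
  if (n <= q) {
    warning(sprintf(
      "n (%d) <= number of covariates (%d): conditional covariance may be degenerate",
      n, q
    ))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S_XX <- crossprod(Xc) / n
  S_XY <- crossprod(Xc, Yc) / n
  e <- eigen(S_XX, symmetric = TRUE)
  keep <- e$values > pinv_tol * max(e$values, .Machine$double.eps)
  if (any(keep)) {
    U <- e$vectors[, keep, drop = FALSE]
    Sxx_pinv <- U %*% (t(U) / e$values[keep])
    S <- S_YY - crossprod(S_XY, Sxx_pinv %*% S_XY)
  } else {
    S <- S_YY
  }
  (S + t(S)) / 2
}

#' Conditional covariance front end
#'
#' Dispatches between the unconditional sample covariance
#' (\code{kernel = "none"} or no covariates), the linear closed form and the
#' general kernel estimator.
#'
#' @inheritParams linear_cond_cov
#' @param kernel one of \code{"linear"}, \code{"rbf"}, \code{"polynomial"},
#'   \code{"none"}.
#' @param ... passed to \code{\link{make_kernel}}.
#' @return p x p conditional covariance estimate.
#' @export
cond_cov <- function(Y, X = NULL,
                     kernel = c("linear", "rbf", "polynomial", "none"), ...) {
  kernel <- match.arg(kernel)
  if (kernel == "none" || is.null(X) || NCOL(X) == 0) {
    return(linear_cond_cov(Y, NULL))
  }
  if (kernel == "linear") {
    return(linear_cond_cov(Y, X))
  }
  kernel_cond_cov(Y, make_kernel(X, kind = kernel, ...))
}
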