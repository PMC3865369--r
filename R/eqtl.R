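#' Single-marker LOD scan
#'
#' For every gene-marker pair, the LOD score of the single-marker regression
#' with intercept: \eqn{(n/2)\log_{10}(RSS_0/RSS_1)}, where \eqn{RSS_0} is
#' the intercept-only residual sum of squares. Computed through the squared
#' correlation (\eqn{RSS_1 = RSS_0 (1 - r^2)}), so the statistic is
#' invariant to location-scale changes of the expression values.
#' Monomorphic markers (no genotype variation) score 0 with a warning;
#' numerically perfect fits are capped.
#'
#' @param Y n x p expression matrix (samples in rows).
#' @param X n x q genotype matrix (0/1 backcross coding, or any numeric
#'   single-locus coding).
#' @param cap upper bound for the statistic on (near-)perfect fits
#'   (default 50).
#' @return p x q matrix of nonnegative LOD scores.
#' @export
single_marker_scan <- function(Y, X, cap = 50) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, n >= 3)
  sdx <- apply(X, 2, stats::sd)
  mono <- sdx == 0
  if (any(mono)) {
    warning("monomorphic marker(s): ",
            paste(colnames(X)[mono], collapse = ", "),
            " (statistic set to 0)")
  }
  sdy <- apply(Y, 2, stats::sd)
  r2 <- matrix(0, ncol(Y), ncol(X),
               dimnames = list(colnames(Y), colnames(X)))
  ok <- !mono & TRUE
  if (any(ok) && all(sdy > 0)) {
    r2[, ok] <- stats::cor(Y, X[, ok, drop = FALSE])^2
  } else if (any(ok)) {
    oky <- sdy > 0
    r2[oky, ok] <- stats::cor(Y[, oky, drop = FALSE], X[, ok, drop = FALSE])^2
  }
  r2[!is.finite(r2)] <- 0
  perfect <- r2 >= 1 - 1e-12
  if (any(perfect)) {
    warning(sum(perfect), " perfect fit(s); LOD capped at ", cap)
  }
  lod <- -(n / 2) * log10(pmax(1 - r2, .Machine$double.eps))
  lod[perfect] <- cap
  pmin(lod, cap)
}

#' Genome-wide permutation threshold for one gene
#'
#' Permutes the gene's expression vector across samples (the marker matrix
#' stays fixed), records each permutation's maximum LOD over all markers,
#' and returns the empirical \eqn{1-\alpha} quantile of that maximum
#' distribution -- the genome-wide significance threshold of the
#' single-marker scan.
#'
#' @param y length-n expression vector of one gene.
#' @param X n x q genotype matrix.
#' @param n_perm number of permutations (>= 20; default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param cap LOD cap, see \code{\link{single_marker_scan}}.
#' @param seed optional integer seed for the permutation stream.
#' @return positive scalar threshold.
#' @export
permutation_threshold <- function(y, X, n_perm = 1000, alpha = 0.05,
                                  cap = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 20) stop("n_perm must be at least 20 for a stable quantile")
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, alpha > 0, alpha <= 1)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  maxs <- .perm_max_lod(matrix(y, ncol = 1), X, P, cap)[, 1]
  unname(stats::quantile(maxs, probs = 1 - alpha, type = 7))
}

# Max-over-markers LOD for permuted expression columns.
# Yg: n x g matrix of genes; P: n x n_perm matrix of row permutations
# (shared across genes); returns n_perm x g matrix of max LOD scores.
.perm_max_lod <- function(Yg, X, P, cap = 50) {
  n <- nrow(Yg)
  Xc <- scale(X)
  Xc[, !is.finite(colSums(Xc))] <- 0
  Yc <- scale(Yg)
  Yc[, !is.finite(colSums(Yc))] <- 0
  n_perm <- ncol(P)
  out <- matrix(0, n_perm, ncol(Yg))
  for (i in seq_len(n_perm)) {
    r <- crossprod(Yc[P[, i], , drop = FALSE], Xc) / (n - 1)
    r2 <- pmin(r^2, 1 - 1e-12)
    lod <- -(n / 2) * log10(1 - r2)
    out[i, ] <- apply(pmin(lod, cap), 1, max)
  }
  out
}

#' Permutation-calibrated covariate selection
#'
#' Mirrors the real-data workflow: scan every gene against every marker in
#' each condition, compute each gene's genome-wide permutation threshold,
#' and take the union over genes of the markers whose LOD exceeds the
#' gene's threshold. The resulting per-condition marker sets are the
#' covariates handed to the conditional covariance estimator; an empty set
#' degenerates the downstream fit to an unconditional GGM.
#'
#' @param Y_list list of T expression matrices (samples x genes), or a
#'   single matrix for one condition.
#' @param X n x q genotype matrix with column names.
#' @param n_perm,alpha,cap,seed see \code{\link{permutation_threshold}}.
#' @return list of T integer vectors of selected marker column indices
#'   (named by marker when \code{X} has column names), plus per-condition
#'   attributes \code{"lod"} (the scan matrix) and \code{"thresholds"}.
#' @export
select_covariates <- function(Y_list, X, n_perm = 1000, alpha = 0.05,
                              cap = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(Y_list) || is.data.frame(Y_list)) Y_list <- list(Y_list)
  X <- as.matrix(X)
  lapply(Y_list, function(Y) {
    Y <- as.matrix(Y)
    lod <- suppressWarnings(single_marker_scan(Y, X, cap))
    n <- nrow(Y)
    P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    maxs <- .perm_max_lod(Y, X, P, cap)
    thr <- apply(maxs, 2, stats::quantile, probs = 1 - alpha, type = 7)
    sel <- sort(unique(unlist(lapply(seq_len(nrow(lod)), function(g) {
      which(lod[g, ] > thr[g])
    }))))
    if (!is.null(colnames(X))) names(sel) <- colnames(X)[sel]
    attr(sel, "lod") <- lod
    attr(sel, "thresholds") <- thr
    sel
  })
}
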