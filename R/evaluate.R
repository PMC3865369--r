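#' Edge indicator of an estimated precision matrix
#'
#' @param Omega precision matrix.
#' @param edge_tol magnitude below which an off-diagonal entry counts as
#'   zero (default 1e-6, far below the Unif(0.5, 1) scale of simulated
#'   signals).
#' @return p x p logical matrix, zero diagonal.
#' @export
precision_edges <- function(Omega, edge_tol = 1e-6) {
  E <- abs(Omega) > edge_tol
  diag(E) <- FALSE
  E
}

.as_omega_list <- function(x) if (inherits(x, "jcggm_fit")) x$omegas else x

#' False positive and false negative edge-recovery rates
#'
#' Averaged over conditions on the lower-triangle pairs \eqn{i > j}:
#' FP is the fraction of truly absent edges that are estimated present,
#' FN the fraction of true edges that are missed.
#'
#' @param est list of T estimated precision matrices (or a
#'   \code{jcggm_fit}).
#' @param truth list of T true adjacency (or precision) matrices; any
#'   nonzero off-diagonal entry is a true edge.
#' @param edge_tol estimate zero threshold.
#' @return named vector \code{c(fp, fn)}.
#' @export
fp_fn_rates <- function(est, truth, edge_tol = 1e-6) {
  est <- .as_omega_list(est)
  T_ <- length(est)
  stopifnot(length(truth) == T_)
  fp <- fn <- numeric(T_)
  for (t in seq_len(T_)) {
    lt <- lower.tri(est[[t]])
    e <- abs(est[[t]][lt]) > edge_tol
    a <- truth[[t]][lt] != 0
    if (!any(!a)) stop("condition ", t, " has no true zeros; FP undefined")
    if (!any(a)) stop("condition ", t, " has no true edges; FN undefined")
    fp[t] <- sum(e & !a) / sum(!a)
    fn[t] <- sum(!e & a) / sum(a)
  }
  c(fp = mean(fp), fn = mean(fn))
}

#' Common-zero false positive and false negative rates
#'
#' Joint versions of the rates: FPC is the fraction of pairs that are zero
#' in every condition's truth but estimated nonzero in at least one
#' condition; FNC the fraction of pairs with a true edge in at least one
#' condition but estimated zero in all of them.
#'
#' @inheritParams fp_fn_rates
#' @return named vector \code{c(fpc, fnc)}.
#' @export
common_zero_rates <- function(est, truth, edge_tol = 1e-6) {
  est <- .as_omega_list(est)
  T_ <- length(est)
  stopifnot(length(truth) == T_)
  lt <- lower.tri(est[[1]])
  true_any <- Reduce(`|`, lapply(truth, function(A) A[lt] != 0))
  est_any <- Reduce(`|`, lapply(est, function(O) abs(O[lt]) > edge_tol))
  common_zero <- !true_any
  if (!any(common_zero)) stop("truth has no common zeros; FPC undefined")
  if (!any(true_any)) stop("truth has no edges in any condition; FNC undefined")
  c(
    fpc = sum(common_zero & est_any) / sum(common_zero),
    fnc = sum(true_any & !est_any) / sum(true_any)
  )
}

#' Relative Frobenius loss
#'
#' \deqn{\mathrm{RFL} = \frac1T \sum_t
#'   \|\Omega^{(t)} - \hat\Omega^{(t)}\|_F^2 / \|\Omega^{(t)}\|_F^2.}
#'
#' @param est list of T estimated precision matrices (or a
#'   \code{jcggm_fit}).
#' @param truth list of T true precision matrices.
#' @return nonnegative scalar.
#' @export
relative_frobenius_loss <- function(est, truth) {
  est <- .as_omega_list(est)
  T_ <- length(est)
  stopifnot(length(truth) == T_)
  mean(vapply(seq_len(T_), function(t) {
    norm(truth[[t]] - est[[t]], "F")^2 / norm(truth[[t]], "F")^2
  }, numeric(1)))
}

#' Compute all five comparison criteria for one fitted model
#'
#' @param est list of T estimated precisions (or \code{jcggm_fit}).
#' @param adjacencies list of T true adjacency matrices.
#' @param omegas list of T true precision matrices.
#' @param edge_tol estimate zero threshold.
#' @return named vector \code{c(fp, fn, fpc, fnc, rfl)}.
#' @export
metric_report <- function(est, adjacencies, omegas, edge_tol = 1e-6) {
  c(
    fp_fn_rates(est, adjacencies, edge_tol),
    common_zero_rates(est, adjacencies, edge_tol),
    rfl = relative_frobenius_loss(est, omegas)
  )
}

#' ROC path of the joint fit along a lambda grid
#'
#' Fits the joint model at every grid value (warm-started, no BIC
#' selection) and records the mean-over-conditions true and false positive
#' rates against the truth, giving one ROC point per lambda. Large lambda
#' gives the empty graph (near the origin); small lambda approaches the
#' dense graph.
#'
#' @inheritParams select_lambda
#' @param truth list of T true adjacency matrices.
#' @param fits optional list of pre-computed \code{jcggm_fit}s matching
#'   \code{lam_grid} (e.g. from \code{\link{select_lambda}}), to avoid
#'   refitting.
#' @return data frame with columns \code{lam}, \code{fpr}, \code{tpr},
#'   sorted by increasing \code{fpr}.
#' @export
roc_path <- function(sigmas, n_ts, truth, lam_grid = NULL, epsilon = 1e-3,
                     edge_tol = 1e-6, fits = NULL, ...) {
  if (is.null(lam_grid)) {
    lam_grid <- default_lambda_grid(sigmas, n_ts, epsilon)
  }
  if (length(lam_grid) == 0) stop("empty lambda grid")
  if (is.null(fits)) {
    warm <- NULL
    fits <- vector("list", length(lam_grid))
    for (i in seq_along(lam_grid)) {
      fits[[i]] <- fit_jcggm(sigmas, n_ts, lam = lam_grid[i],
                             epsilon = epsilon, omegas0 = warm, ...)
      warm <- fits[[i]]$omegas
    }
  }
  pts <- t(vapply(fits, function(f) {
    r <- fp_fn_rates(f$omegas, truth, edge_tol)
    c(fpr = unname(r["fp"]), tpr = 1 - unname(r["fn"]))
  }, c(fpr = 0, tpr = 0)))
  out <- data.frame(lam = lam_grid, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Benchmark the four estimators on simulated replicates
#'
#' Runs the full study pipeline on fresh replicates of a simulation
#' scenario and scores each requested method with the five criteria.
#' Methods: \code{"GGM"} (per-condition glasso on the marginal
#' covariance), \code{"CGGM"} (per-condition glasso on the linear-kernel
#' conditional covariance), \code{"JGGM"} (joint truncated-log fit on
#' marginal covariances) and \code{"JCGGM"} (joint fit on conditional
#' covariances). All methods are BIC-tuned on the same grids conventions.
#'
#' @inheritParams run_scenario
#' @param methods subset of \code{c("GGM", "CGGM", "JGGM", "JCGGM")}.
#' @param epsilon truncation point of the joint penalty.
#' @param edge_tol estimate zero threshold.
#' @param lla_max_iter LLA iteration cap for the joint fits.
#' @param verbose print one line per replicate.
#' @return data frame with one row per replicate x method and columns
#'   \code{rep}, \code{method}, \code{fp}, \code{fn}, \code{fpc},
#'   \code{fnc}, \code{rfl}.
#' @export
run_benchmark <- function(case = c("case1", "case2"), n = 100, n_reps = 10,
                          seed = 1,
                          methods = c("GGM", "CGGM", "JGGM", "JCGGM"),
                          epsilon = 1e-3, edge_tol = 1e-6,
                          lla_max_iter = 50, verbose = FALSE) {
  case <- match.arg(case)
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- run_scenario(case, n = n, n_reps = n_reps, seed = seed)
  rows <- list()
  for (r in seq_along(reps)) {
    rp <- reps[[r]]
    n_ts <- rep(n, length(rp$Y))
    marg <- lapply(rp$Y, function(Y) linear_cond_cov(Y, NULL))
    cond <- NULL
    if (any(methods %in% c("CGGM", "JCGGM"))) {
      cond <- suppressWarnings(lapply(rp$Y, function(Y) linear_cond_cov(Y, rp$X)))
    }
    for (m in methods) {
      est <- switch(m,
        GGM = fit_separate_glasso(marg, n_ts, edge_tol = edge_tol)$omegas,
        CGGM = fit_separate_glasso(cond, n_ts, edge_tol = edge_tol)$omegas,
        JGGM = select_lambda(marg, n_ts, epsilon = epsilon,
                             edge_tol = edge_tol,
                             lla_max_iter = lla_max_iter)$fit$omegas,
        JCGGM = select_lambda(cond, n_ts, epsilon = epsilon,
                              edge_tol = edge_tol,
                              lla_max_iter = lla_max_iter)$fit$omegas
      )
      met <- metric_report(est, rp$adjacencies, rp$omegas, edge_tol)
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, method = m, fp = met[["fp"]], fn = met[["fn"]],
        fpc = met[["fpc"]], fnc = met[["fnc"]], rfl = met[["rfl"]]
      )
    }
    if (verbose) {
      message(sprintf("replicate %d/%d done", r, length(reps)))
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark as mean (standard error) per method
#'
#' @param bench data frame from \code{\link{run_benchmark}}.
#' @return data frame with one row per method and \code{<metric>_mean},
#'   \code{<metric>_se} columns (se = sd / sqrt(replicates)).
#' @export
summarize_benchmark <- function(bench) {
  mets <- c("fp", "fn", "fpc", "fnc", "rfl")
  out <- lapply(split(bench, bench$method), function(d) {
    row <- data.frame(method = d$method[1], n_reps = nrow(d))
    for (m in mets) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_se")]] <- stats::sd(d[[m]]) / sqrt(nrow(d))
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
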