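#' Equally spaced single-chromosome genetic map
#'
#' @param q number of markers.
#' @param length_cM chromosome length in centiMorgans; markers are placed
#'   equally spaced on \code{[0, length_cM]} inclusive.
#' @return a \code{genetic_map} data frame with columns \code{marker},
#'   \code{chr}, \code{pos}.
#' @export
sim_map <- function(q = 10, length_cM = 1000) {
  stopifnot(q >= 1, length_cM >= 0)
  pos <- if (q == 1) 0 else seq(0, length_cM, length.out = q)
  genetic_map(data.frame(
    marker = sprintf("M%d", seq_len(q)),
    chr = "1",
    pos = pos,
    stringsAsFactors = FALSE
  ))
}

#' Validate a genetic map
#'
#' @param df data frame with columns \code{marker}, \code{chr}, \code{pos}
#'   (position in cM, nonnegative, non-decreasing within a chromosome).
#' @return the validated data frame with class \code{genetic_map}.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("marker", "chr", "pos") %in% names(df)))
  if (anyDuplicated(df$marker)) {
    stop("duplicate marker ids: ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  }
  if (any(df$pos < 0)) stop("marker positions must be nonnegative cM")
  for (ch in unique(df$chr)) {
    if (is.unsorted(df$pos[df$chr == ch])) {
      stop("marker positions must be non-decreasing within chromosome ", ch)
    }
  }
  class(df) <- c("genetic_map", class(df))
  df
}

#' Simulate backcross genotypes on a genetic map
#'
#' Genotypes are 0/1 (the two backcross classes). The first marker of each
#' chromosome is Bernoulli(1/2); consecutive markers recombine with the
#' Haldane fraction \eqn{r = (1 - e^{-2d/100})/2} for inter-marker distance
#' \eqn{d} cM, so tightly linked markers are nearly identical and distant
#' markers approach independence (\eqn{r \to 1/2}).
#'
#' @param n number of individuals.
#' @param map a \code{\link{genetic_map}} (default \code{\link{sim_map}()}).
#' @return n x q integer matrix of 0/1 genotypes, columns named by marker.
#' @export
simulate_backcross <- function(n, map = sim_map()) {
  stopifnot(n >= 1)
  if (nrow(map) == 0) stop("empty genetic map")
  q <- nrow(map)
  G <- matrix(0L, n, q, dimnames = list(NULL, map$marker))
  col <- 1L
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    g <- stats::rbinom(n, 1L, 0.5)
    G[, idx[1]] <- g
    if (length(idx) > 1) {
      d <- diff(map$pos[idx])
      r <- 0.5 * (1 - exp(-2 * d / 100))
      for (j in seq_along(d)) {
        flip <- stats::rbinom(n, 1L, r[j])
        g <- as.integer(xor(g, flip))
        G[, idx[j + 1]] <- g
      }
    }
  }
  G
}

#' Scale-free network structure with condition-specific additions
#'
#' Grows a common scale-free graph by preferential attachment in the
#' Barabasi-Albert fashion: the seed is a path on \code{n0 = n_edges_seed + 1}
#' nodes (so the seed contains exactly \code{n_edges_seed} edges), and each
#' of the remaining \code{p - n0} nodes is attached by one edge to an
#' existing node chosen with probability proportional to its current degree.
#' The common structure therefore has \eqn{M = n\_edges\_seed + (p - n0)}
#' edges. Each of the T conditions then receives
#' \code{round(0.1 * M)} additional edges drawn uniformly from the
#' non-edges of the common graph.
#'
#' @param p number of nodes (genes); must exceed the seed size.
#' @param n_conditions number of conditions T.
#' @param n_edges_seed number of edges in the seed path (default 6).
#' @param specific_frac fraction of M added per condition (default 0.1).
#' @return list with \code{common} (p x p binary adjacency),
#'   \code{conditions} (list of T adjacencies, each a superset of
#'   \code{common}), \code{M} (common edge count) and \code{n_specific}.
#' @export
simulate_scale_free <- function(p, n_conditions = 3, n_edges_seed = 6,
                                specific_frac = 0.1) {
  n0 <- n_edges_seed + 1L
  stopifnot(p >= n0 + 1)
  A <- matrix(0L, p, p)
  for (i in seq_len(n0 - 1L)) {
    A[i, i + 1L] <- A[i + 1L, i] <- 1L
  }
  deg <- rowSums(A)
  for (v in seq.int(n0 + 1L, p)) {
    tgt <- sample.int(v - 1L, 1, prob = deg[seq_len(v - 1L)])
    A[v, tgt] <- A[tgt, v] <- 1L
    deg[v] <- 1L
    deg[tgt] <- deg[tgt] + 1L
  }
  M <- sum(A) / 2L
  k <- floor(specific_frac * M + 0.5)  # round half away from zero
  ut <- which(upper.tri(A))
  free <- ut[A[ut] == 0L]
  conds <- lapply(seq_len(n_conditions), function(t) {
    At <- A
    if (k > 0) {
      add <- sample(free, k)
      At[add] <- 1L
      At <- At + t(At)
      At[At > 1L] <- 1L
    }
    At
  })
  list(common = A, conditions = conds, M = M, n_specific = k)
}

#' Draw a precision matrix on a given network structure
#'
#' Off-diagonal entries on edges are drawn from
#' \eqn{Unif([-1,-0.5]\cup[0.5,1])} (symmetric). Two constructions of the
#' diagonal are available:
#'
#' \describe{
#' \item{\code{"rownorm"} (default)}{row \eqn{i} of the draw is divided by
#'   \code{norm_factor} times its absolute row sum, the result is
#'   symmetrized by averaging with its transpose, and the diagonal is set
#'   to 1 -- the usual row-normalized construction of the
#'   multiple-graphical-model simulation literature. On hub-heavy graphs
#'   the averaging can leave the smallest eigenvalue slightly negative, so
#'   a safeguard shrinks all off-diagonal entries by the common factor that
#'   restores a smallest eigenvalue of \code{eig_margin} whenever it falls
#'   below it. Partial correlations are moderate, so support recovery is a
#'   genuinely hard problem at the study's sample sizes.}
#' \item{\code{"dominant"}}{the diagonal is the row-wise sum of absolute
#'   off-diagonal entries (weak diagonal dominance) and the whole draw is
#'   rejected and repeated until the smallest eigenvalue exceeds
#'   \code{eig_tol}. Note this construction is exactly singular whenever the
#'   graph is cycle-free (a \eqn{\pm1} vector chosen sign-consistently along
#'   the edges attains the Gershgorin bound), so for tree-like graphs the
#'   rejection loop cannot terminate and an error is raised; on graphs with
#'   cycles it produces near-singular matrices with extreme partial
#'   correlations.}
#' }
#' Isolated nodes (degree zero) receive a unit diagonal in both variants.
#'
#' @param adjacency symmetric binary matrix with zero diagonal and at least
#'   one edge.
#' @param method diagonal construction, see Details.
#' @param norm_factor row-normalization factor of \code{"rownorm"}
#'   (default 1.5).
#' @param eig_margin smallest eigenvalue guaranteed by the \code{"rownorm"}
#'   safeguard (default 0.05).
#' @param eig_tol positive-definiteness cutoff on the smallest eigenvalue.
#' @param max_tries rejection-sampling cap (\code{"dominant"} only);
#'   exceeding it raises an error.
#' @return p x p symmetric positive definite matrix whose off-diagonal
#'   support equals the adjacency.
#' @export
build_precision <- function(adjacency, method = c("rownorm", "dominant"),
                            norm_factor = 1.5, eig_margin = 0.05,
                            eig_tol = 1e-8, max_tries = 1000) {
  method <- match.arg(method)
  A <- as.matrix(adjacency)
  p <- nrow(A)
  stopifnot(ncol(A) == p, all(A %in% c(0, 1)), all(diag(A) == 0),
            isTRUE(all.equal(A, t(A))))
  ut_edges <- which(upper.tri(A) & A == 1)
  if (length(ut_edges) == 0) stop("adjacency has no edges")
  for (try in seq_len(max_tries)) {
    O <- matrix(0, p, p)
    vals <- stats::runif(length(ut_edges), 0.5, 1) *
      sample(c(-1, 1), length(ut_edges), replace = TRUE)
    O[ut_edges] <- vals
    O <- O + t(O)
    if (method == "rownorm") {
      rs <- rowSums(abs(O))
      rs[rs == 0] <- 1
      O <- O / (norm_factor * rs)   # divide row i by norm_factor * rowsum_i
      O <- (O + t(O)) / 2
      diag(O) <- 1
      m <- min(eigen(O, symmetric = TRUE, only.values = TRUE)$values)
      if (m < eig_margin) {
        # shrink off-diagonals so the smallest eigenvalue equals eig_margin
        shrink <- (1 - eig_margin) / (1 - m)
        O <- O * shrink
        diag(O) <- 1
      }
    } else {
      d <- rowSums(abs(O))
      d[d == 0] <- 1  # isolated nodes: unit variance scale
      diag(O) <- d
    }
    ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > eig_tol) return(O)
  }
  stop("could not draw a positive definite precision matrix in ",
       max_tries, " tries (pathological adjacency)")
}

#' Simulate expression data from the marker-effect model
#'
#' \eqn{Y = X B^T + E}, rows of \eqn{E} i.i.d. \eqn{N_p(0, \Omega^{-1})}
#' (sampled by back-substitution with the Cholesky factor of \eqn{\Omega}).
#'
#' @param X n x q genotype/covariate matrix.
#' @param B p x q coefficient matrix (genes by markers).
#' @param Omega p x p positive definite precision matrix of the noise.
#' @return n x p expression matrix.
#' @export
simulate_expression <- function(X, B, Omega) {
  X <- as.matrix(X)
  B <- as.matrix(B)
  n <- nrow(X)
  p <- nrow(B)
  stopifnot(ncol(B) == ncol(X), nrow(Omega) == p, ncol(Omega) == p)
  U <- tryCatch(chol(Omega), error = function(e) {
    stop("Omega must be positive definite: ", conditionMessage(e))
  })
  Z <- matrix(stats::rnorm(n * p), n, p)
  E <- t(backsolve(U, t(Z)))  # rows have covariance Omega^{-1}
  X %*% t(B) + E
}

.case1_triples <- list(
  c(-0.09, 0.789, -0.667),
  c(1.361, 1.508, -2.608),
  c(0.687, 0.316, 2.020)
)
.case_positions <- cbind(gene = c(1L, 2L, 3L), marker = c(1L, 4L, 8L))
.case2_blocks <- list(1:18, 19:25, 26:30)

#' Case-1 coefficient matrices: three isolated marker effects
#'
#' Each condition has exactly three nonzero coefficients, at gene-marker
#' positions (1,1), (2,4) and (3,8); the values are fixed per condition:
#' (-0.09, 0.789, -0.667), (1.361, 1.508, -2.608) and (0.687, 0.316, 2.020).
#' This is the scenario with essentially no confounding of the gene-gene
#' network by markers, where conditioning brings no advantage.
#'
#' @param p,q dimensions of each coefficient matrix (genes x markers).
#' @return list of 3 deterministic p x q matrices.
#' @export
make_case1_B <- function(p = 30, q = 10) {
  stopifnot(p >= 3, q >= 8)
  lapply(.case1_triples, function(v) {
    B <- matrix(0, p, q)
    B[.case_positions] <- v
    B
  })
}

#' Case-2 coefficient matrices: eQTL hotspots
#'
#' Genes 1-18 load on marker 1, genes 19-25 on marker 4 and genes 26-30 on
#' marker 8. Within each block the coefficient is the corresponding Case-1
#' value for that condition perturbed by independent \eqn{N(0, 0.1^2)}
#' noise, so every gene is marker-driven and markers induce strong marginal
#' gene-gene correlations that an unconditional model mistakes for edges.
#'
#' @param sd_perturb standard deviation of the coefficient perturbation.
#' @return list of 3 random 30 x 10 matrices (30 nonzeros each).
#' @export
make_case2_B <- function(sd_perturb = 0.1) {
  lapply(.case1_triples, function(v) {
    B <- matrix(0, 30, 10)
    for (b in seq_along(.case2_blocks)) {
      genes <- .case2_blocks[[b]]
      B[genes, .case_positions[b, "marker"]] <-
        v[b] + stats::rnorm(length(genes), 0, sd_perturb)
    }
    B
  })
}

#' Generate replicates of a full simulation scenario
#'
#' One replicate draws fresh genotypes (backcross on a fixed 1000 cM map
#' with 10 equally spaced markers), a fresh common scale-free network with
#' condition-specific additions, fresh precision matrices on each
#' condition's structure, the case's coefficient matrices, and expression
#' data \eqn{Y^{(t)} = X B^{(t)T} + E^{(t)}}. Everything except the map is
#' redrawn per replicate. The stream is deterministic given \code{seed}.
#'
#' @param case \code{"case1"} (sparse marker effects) or \code{"case2"}
#'   (hotspots).
#' @param n per-condition sample size (the study uses 30 and 100).
#' @param n_reps number of independent replicates.
#' @param seed integer master seed.
#' @param p,q,n_conditions scenario dimensions (defaults 30 genes,
#'   10 markers, 3 conditions).
#' @return list of \code{n_reps} replicates; each has \code{X} (genotypes),
#'   \code{Y} (list of T expression matrices), \code{B}, \code{omegas}
#'   (true precisions), \code{adjacencies} (per-condition truth),
#'   \code{common_adj} and \code{map}.
#' @export
run_scenario <- function(case = c("case1", "case2"), n = 100, n_reps = 1,
                         seed = 1, p = 30, q = 10, n_conditions = 3) {
  case <- match.arg(case)
  if (case == "case2") stopifnot(p == 30, q == 10)
  map <- sim_map(q = q, length_cM = 1000)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  lapply(seq_len(n_reps), function(r) {
    set.seed(rep_seeds[r])
    X <- simulate_backcross(n, map)
    net <- simulate_scale_free(p, n_conditions = n_conditions)
    omegas <- lapply(net$conditions, build_precision)
    B <- if (case == "case1") make_case1_B(p, q) else make_case2_B()
    Y <- lapply(seq_len(n_conditions), function(t) {
      simulate_expression(X, B[[t]], omegas[[t]])
    })
    names(Y) <- sprintf("condition%d", seq_len(n_conditions))
    list(X = X, Y = Y, B = B, omegas = omegas,
         adjacencies = net$conditions, common_adj = net$common, map = map)
  })
}
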