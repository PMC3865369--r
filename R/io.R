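.sniff_sep <- function(path) {
  line <- readLines(path, n = 1)
  if (length(line) == 0) stop("empty file: ", path)
  n_tab <- lengths(regmatches(line, gregexpr("\t", line)))
  n_com <- lengths(regmatches(line, gregexpr(",", line)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read one condition's expression matrix
#'
#' Reads a TSV (comma-separated accepted, sniffed from the header line)
#' with a header row and a leading id column, and returns a numeric matrix
#' with samples in rows and genes in columns regardless of the on-disk
#' orientation. Missing values, non-numeric cells and duplicate ids are
#' load-time errors naming the offending cell or id.
#'
#' @param path file path.
#' @param orientation \code{"samples_rows"} (default: rows are samples,
#'   header names are genes) or \code{"genes_rows"} (transposed on disk).
#' @return numeric matrix, samples x genes, with sample ids as row names
#'   and gene ids as column names.
#' @export
read_expression <- function(path, orientation = c("samples_rows", "genes_rows")) {
  orientation <- match.arg(orientation)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected an id column plus at least one data column in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn)) {
    stop("duplicate column ids in ", path, ": ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  M <- matrix(NA_real_, nrow(df), length(cn), dimnames = list(ids, cn))
  for (j in seq_along(cn)) {
    v <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | v %in% c("NA", "NaN", ""))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing value at row '%s', column '%s' in %s",
                   ids[bad[1]], cn[j], path))
    }
    M[, j] <- num
  }
  if (orientation == "genes_rows") M <- t(M)
  M
}

#' Read a covariate (genotype) matrix
#'
#' Same dialect as \code{\link{read_expression}} (samples in rows, markers
#' in columns). With \code{coding = "backcross01"} every entry must be 0
#' or 1.
#'
#' @param path file path.
#' @param coding \code{"backcross01"} or \code{"numeric"}.
#' @return numeric matrix, samples x markers.
#' @export
read_covariates <- function(path, coding = c("backcross01", "numeric")) {
  coding <- match.arg(coding)
  X <- read_expression(path, "samples_rows")
  if (coding == "backcross01" && !all(X %in% c(0, 1))) {
    bad <- which(matrix(!(X %in% c(0, 1)), nrow(X)), arr.ind = TRUE)[1, ]
    stop(sprintf("backcross01 coding violated at row '%s', column '%s' in %s",
                 rownames(X)[bad[1]], colnames(X)[bad[2]], path))
  }
  attr(X, "coding") <- coding
  X
}

#' Read a genetic map file
#'
#' Expects columns \code{marker}, \code{chr}, \code{pos} (cM).
#'
#' @param path file path (TSV/CSV).
#' @return a validated \code{\link{genetic_map}}.
#' @export
read_genetic_map <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("marker", "chr", "pos") %in% names(df))) {
    stop("genetic map must have columns marker, chr, pos")
  }
  df$pos <- as.numeric(df$pos)
  if (anyNA(df$pos)) stop("non-numeric position in genetic map ", path)
  genetic_map(df[, c("marker", "chr", "pos")])
}

#' Bundle per-condition expression matrices into a condition panel
#'
#' Validates that all conditions share the same genes in the same order,
#' that every condition has at least two samples and two genes, and that no
#' values are missing.
#'
#' @param Y_list named list of T samples x genes matrices (names are the
#'   condition labels).
#' @return object of class \code{condition_panel}: list with
#'   \code{conditions}, \code{Y}, \code{gene_ids}, \code{sample_ids}.
#' @export
condition_panel <- function(Y_list) {
  stopifnot(is.list(Y_list), length(Y_list) >= 1)
  labels <- names(Y_list)
  if (is.null(labels) || any(labels == "")) {
    labels <- sprintf("condition%d", seq_along(Y_list))
  }
  Y_list <- lapply(Y_list, as.matrix)
  genes <- colnames(Y_list[[1]])
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(Y_list[[1]])))
  for (i in seq_along(Y_list)) {
    Y <- Y_list[[i]]
    if (nrow(Y) < 2) stop("condition ", labels[i], " has fewer than 2 samples")
    if (ncol(Y) < 2) stop("condition ", labels[i], " has fewer than 2 genes")
    if (anyNA(Y)) stop("missing values in condition ", labels[i])
    g <- colnames(Y)
    if (!is.null(g) && !identical(g, genes)) {
      stop("gene ids of condition ", labels[i],
           " do not match the first condition (same genes, same order required)")
    }
  }
  structure(
    list(
      conditions = labels,
      Y = stats::setNames(Y_list, labels),
      gene_ids = genes,
      sample_ids = lapply(Y_list, rownames)
    ),
    class = "condition_panel"
  )
}

#' @export
print.condition_panel <- function(x, ...) {
  cat(sprintf("Condition panel: T = %d, p = %d genes\n",
              length(x$Y), length(x$gene_ids)))
  for (i in seq_along(x$Y)) {
    cat(sprintf("  %s: n = %d samples\n", x$conditions[i], nrow(x$Y[[i]])))
  }
  invisible(x)
}

#' Align covariate rows to a condition's samples by id
#'
#' Matching is by sample id, never by row order; samples present in the
#' expression matrix but absent from the covariates are an error.
#'
#' @param X covariate matrix with sample row names.
#' @param sample_ids character vector of the condition's sample ids.
#' @return \code{X} reordered to \code{sample_ids}.
#' @export
align_covariates <- function(X, sample_ids) {
  if (is.null(rownames(X)) || is.null(sample_ids)) {
    stop("sample ids are required on both the covariates and the expression data")
  }
  miss <- setdiff(sample_ids, rownames(X))
  if (length(miss) > 0) {
    stop("samples missing from covariates: ", paste(miss, collapse = ", "))
  }
  X[sample_ids, , drop = FALSE]
}

#' Write per-condition edge lists from a fitted precision set
#'
#' One TSV per condition with columns \code{gene_i}, \code{gene_j}
#' (\eqn{i < j}) and the partial correlation
#' \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}}, restricted to entries
#' with \eqn{|\omega_{ij}|} above the threshold; plus one combined TSV
#' flagging, for the union of all edges, per-condition presence (0/1).
#'
#' @param omegas list of T precision matrices (or a \code{jcggm_fit}).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"edges"}).
#' @param threshold positive magnitude threshold (default 1e-6).
#' @param gene_ids optional gene names (default from matrix dimnames or
#'   \code{g1..gp}).
#' @param conditions optional condition labels.
#' @return invisibly, the vector of written file paths.
#' @export
write_edge_list <- function(omegas, dir, prefix = "edges", threshold = 1e-6,
                            gene_ids = NULL, conditions = NULL) {
  omegas <- .as_omega_list(omegas)
  stopifnot(threshold > 0)
  T_ <- length(omegas)
  p <- nrow(omegas[[1]])
  if (is.null(gene_ids)) {
    gene_ids <- colnames(omegas[[1]])
    if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(p))
  }
  if (is.null(conditions)) conditions <- sprintf("condition%d", seq_len(T_))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ui <- which(upper.tri(omegas[[1]]), arr.ind = TRUE)  # row < col
  paths <- character(0)
  present <- matrix(FALSE, nrow(ui), T_)
  pcors <- matrix(NA_real_, nrow(ui), T_)
  for (t in seq_len(T_)) {
    O <- omegas[[t]]
    if (any(diag(O) <= 0)) {
      stop("non-positive diagonal in precision matrix of condition ",
           conditions[t], " (invalid precision)")
    }
    d <- sqrt(diag(O))
    w <- O[ui]
    pc <- -w / (d[ui[, 1]] * d[ui[, 2]])
    keep <- abs(w) > threshold
    present[, t] <- keep
    pcors[, t] <- pc
    df <- data.frame(
      gene_i = gene_ids[ui[keep, 1]],
      gene_j = gene_ids[ui[keep, 2]],
      partial_cor = pc[keep]
    )
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, conditions[t]))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  any_edge <- rowSums(present) > 0
  comb <- data.frame(
    gene_i = gene_ids[ui[any_edge, 1]],
    gene_j = gene_ids[ui[any_edge, 2]]
  )
  for (t in seq_len(T_)) comb[[conditions[t]]] <- as.integer(present[any_edge, t])
  f <- file.path(dir, sprintf("%s_combined.tsv", prefix))
  utils::write.table(comb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, f))
}

#' Write a dense precision matrix as TSV
#'
#' @param Omega p x p matrix.
#' @param path output path.
#' @param gene_ids optional names for rows/columns.
#' @export
write_precision_tsv <- function(Omega, path, gene_ids = NULL) {
  p <- nrow(Omega)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(Omega)
    if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(p))
  }
  df <- data.frame(id = gene_ids, Omega, check.names = FALSE)
  colnames(df) <- c("id", gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the joint conditional model on a condition panel
#'
#' End-to-end convenience wrapper: estimates each condition's conditional
#' covariance given its covariates (aligned by sample id), then runs the
#' BIC-tuned joint fit.
#'
#' @param panel a \code{\link{condition_panel}}.
#' @param X covariate matrix shared by all conditions (rows named by
#'   sample), a list of per-condition matrices, or NULL for the
#'   unconditional model.
#' @param kernel conditional covariance kernel, see \code{\link{cond_cov}}.
#' @param epsilon truncated-log penalty parameter.
#' @param ... passed to \code{\link{select_lambda}}.
#' @return the \code{\link{select_lambda}} result, with the conditional
#'   covariances attached as \code{sigmas} and sample sizes as \code{n_ts}.
#' @export
jcggm_panel <- function(panel, X = NULL, kernel = "linear",
                        epsilon = 1e-3, ...) {
  stopifnot(inherits(panel, "condition_panel"))
  T_ <- length(panel$Y)
  Xs <- if (is.null(X) || is.list(X)) X else rep(list(X), T_)
  sigmas <- lapply(seq_len(T_), function(t) {
    Y <- panel$Y[[t]]
    Xt <- if (is.null(Xs)) NULL else Xs[[t]]
    if (!is.null(Xt) && !is.null(rownames(Y))) {
      Xt <- align_covariates(Xt, rownames(Y))
    }
    cond_cov(Y, Xt, kernel = kernel)
  })
  n_ts <- vapply(panel$Y, nrow, 1L)
  res <- select_lambda(sigmas, n_ts, epsilon = epsilon, ...)
  res$sigmas <- sigmas
  res$n_ts <- n_ts
  res$gene_ids <- panel$gene_ids
  res$conditions <- panel$conditions
  res
}
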