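#' Fit surprisal analysis to a single-cell expression matrix
#'
#' Decomposes the natural log of the intensities into a reference (steady)
#' state term plus unbalanced-process terms,
#' \deqn{\ln(X_i(cell) + offset) = \sum_{\alpha \ge 0} G_{i\alpha}\,\lambda_\alpha(cell),}
#' where the \eqn{\alpha = 0} term is the reference state, `G[, alpha]` holds
#' the marker weights (degree of participation) of process \eqn{\alpha} and
#' `Lambda[, alpha]` its per-cell amplitudes. The sign inside the exponent of
#' the multiplicative model is absorbed into the stored amplitudes, so
#' reconstruction is a plain sum and the product \eqn{G_{i\alpha}\lambda_\alpha(cell)}
#' is directly the signed log-scale deviation (positive = upregulated by
#' \eqn{\alpha}).
#'
#' The factorization is the SVD of `C = log(values + offset)`, computed
#' through the small n_markers x n_markers matrix `crossprod(C)`: its
#' eigenvectors are the `G` columns, the square roots of its eigenvalues the
#' importance (singular) values, and `Lambda = C %*% G`. Memory and time are
#' linear in the number of cells; the n_cells x n_cells covariance matrix is
#' never formed. With p markers at most p - 1 constraint processes exist
#' (10 for an 11-marker panel); rank deficiency (e.g. a constant marker
#' column) reduces that further, with a warning.
#'
#' Each `G` column's sign is fixed so that its largest-magnitude entry is
#' positive (amplitudes flipped to match), making barcodes reproducible
#' across platforms. Processes are ordered by decreasing importance.
#'
#' @param data a [expression_matrix()].
#' @param offset positive constant added before the log so zero intensities
#'   are admissible; default 1 intensity unit.
#' @param max_processes optional cap on the number of constraint processes
#'   retained (the reference term is always kept).
#' @param rank_tol relative eigenvalue floor (on `crossprod(C)`) defining the
#'   numerical rank (default 1e-12).
#'
#' @return An object of class `csss_decomposition` with elements `G`
#'   (n_markers x (K+1), column 1 = reference pattern), `Lambda`
#'   (n_cells x (K+1)), `importance` (nonincreasing singular values), `K`,
#'   `offset`, `marker_names`, `cell_ids`, `sample_labels`.
#' @examples
#' sim <- generate_cells(rt_scenario_spec(seed = 1,
#'   n_cells = c(control = 300, RT_d6 = 300)))
#' dec <- fit_surprisal(sim$expression)
#' dec$K
#' @export
fit_surprisal <- function(data, offset = 1, max_processes = NULL,
                          rank_tol = 1e-12) {
  stopifnot(inherits(data, "csss_expression"))
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a positive scalar")
  shifted <- data$values + offset
  if (any(shifted <= 0))
    stop("nonpositive value after adding offset; log undefined")
  C <- log(shifted)
  p <- ncol(C)

  eig <- eigen(crossprod(C), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  sv <- sqrt(ev)
  # rank floor on the eigenvalues: eps-level eigenvalue noise surfaces as
  # sqrt(eps)-scale singular values, so flooring sv directly would overcount
  rank <- sum(ev >= rank_tol * ev[1L])
  if (rank < p)
    warning("rank-deficient log matrix (numerical rank ", rank, " < ", p,
            " markers); number of processes reduced to ", rank - 1L)
  K <- rank - 1L
  if (!is.null(max_processes)) K <- min(K, as.integer(max_processes))
  keep <- seq_len(K + 1L)
  G <- eig$vectors[, keep, drop = FALSE]

  # deterministic sign: largest-|entry| component of each G column positive
  for (j in keep) {
    i <- which.max(abs(G[, j]))
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  Lambda <- C %*% G

  cn <- c("reference", if (K > 0) paste0("process_", seq_len(K)))
  dimnames(G) <- list(data$marker_names, cn)
  dimnames(Lambda) <- list(NULL, cn)
  structure(list(G = G, Lambda = Lambda, importance = sv[keep], K = K,
                 offset = offset, marker_names = data$marker_names,
                 cell_ids = data$cell_ids, sample_labels = data$sample_labels),
            class = "csss_decomposition")
}

#' @export
print.csss_decomposition <- function(x, ...) {
  cat("<csss_decomposition> ", nrow(x$Lambda), " cells, ",
      length(x$marker_names), " markers, K = ", x$K,
      " unbalanced processes (offset = ", x$offset, ")\n", sep = "")
  cat("  importance:", paste(signif(x$importance, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Reference-state expression levels
#'
#' The expected expression of each marker in each cell absent all
#' constraints: the back-transformed \eqn{\alpha = 0} term,
#' `exp(Lambda[, 1] %o% G[, 1]) - offset`, clipped at 0.
#'
#' @param dec a `csss_decomposition`.
#' @return n_cells x n_markers matrix of nonnegative reference intensities.
#' @export
reference_state <- function(dec) {
  stopifnot(inherits(dec, "csss_decomposition"))
  r <- exp(tcrossprod(dec$Lambda[, 1L], dec$G[, 1L])) - dec$offset
  r[r < 0] <- 0
  dimnames(r) <- list(NULL, dec$marker_names)
  r
}

#' Log-scale deviations attributable to one process
#'
#' Entry `(cell, i)` is \eqn{G_{i\alpha}\lambda_\alpha(cell)}: the signed
#' log-scale deviation of marker i in that cell due to process `alpha`.
#' A positive product means the marker is upregulated by the process in that
#' cell. Summing over all processes and adding the reference term
#' reconstructs `log(X + offset)` exactly.
#'
#' @param dec a `csss_decomposition`.
#' @param alpha process index, `1 <= alpha <= dec$K`.
#' @return n_cells x n_markers matrix.
#' @export
deviation_terms <- function(dec, alpha) {
  stopifnot(inherits(dec, "csss_decomposition"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 || alpha > dec$K)
    stop("alpha must be a process index in 1..K = ", dec$K)
  d <- tcrossprod(dec$Lambda[, alpha + 1L], dec$G[, alpha + 1L])
  dimnames(d) <- list(NULL, dec$marker_names)
  d
}

#' Write a decomposition as delimited tables
#'
#' Writes `G.tsv` (markers x processes), `lambda.tsv` (cells x processes,
#' with cell ids and condition labels) and `importance.tsv` into `dir`.
#'
#' @param dec a `csss_decomposition`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(dec, dir) {
  stopifnot(inherits(dec, "csss_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- data.table::data.table(marker = dec$marker_names)
  g <- cbind(g, data.table::as.data.table(dec$G))
  data.table::fwrite(g, file.path(dir, "G.tsv"), sep = "\t")
  l <- data.table::data.table(cell_id = dec$cell_ids,
                              condition = dec$sample_labels)
  l <- cbind(l, data.table::as.data.table(dec$Lambda))
  data.table::fwrite(l, file.path(dir, "lambda.tsv"), sep = "\t")
  imp <- data.table::data.table(process = colnames(dec$G),
                                importance = dec$importance)
  data.table::fwrite(imp, file.path(dir, "importance.tsv"), sep = "\t")
  invisible(dir)
}
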