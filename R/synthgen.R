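#' Specify a synthetic single-cell panel with planted structure
#'
#' Defines a forward model in the shape of the surprisal decomposition used
#' generatively: cell intensities are
#' `exp(log(baseline_i) + sum_a G_planted[i, a] * lambda_planted[a, cell] + eps)`
#' with `eps ~ N(0, noise_sigma^2)` i.i.d. per entry. Planted subpopulations
#' are defined by barcodes over the planted processes; a cell active on a
#' process draws its amplitude as `sign * amplitude + N(0, amplitude_cv *
#' amplitude)`, inactive processes get small jitter `N(0, inactive_sd)` so
#' sorted-amplitude curves have a realistic sigmoid body.
#'
#' Cells are allocated to subpopulations deterministically from the mixing
#' fractions (largest-remainder rounding); randomness enters only through
#' amplitudes and noise. Cells not assigned to any planted subpopulation form
#' the steady-state bulk (all-zero barcode).
#'
#' @param baseline positive per-marker reference intensities (arbitrary
#'   fluorescence units); names are used as marker names.
#' @param processes n_markers x P matrix of planted weight vectors; columns
#'   are normalized to unit length. Orthogonal columns (the default produced
#'   by [orthogonal_processes()]) make the planted structure recoverable.
#' @param subpopulations data.frame with columns `name`, `barcode` (string of
#'   `+`/`-`/`0` over the P planted processes) and one numeric fraction
#'   column per condition, named after it. Per-condition fractions must sum
#'   to at most 1.
#' @param n_cells named integer vector: cells per condition.
#' @param amplitude magnitude of an active process amplitude (default 3).
#' @param noise_sigma log-scale Gaussian noise SD (default 0.05).
#' @param inactive_sd jitter SD of inactive-process amplitudes (default 0.2).
#' @param amplitude_cv relative SD of active amplitudes (default 0.1).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return An object of class `csss_synthspec`.
#' @seealso [generate_cells()], [rt_scenario_spec()]
#' @export
synthetic_spec <- function(baseline, processes, subpopulations, n_cells,
                           amplitude = 3, noise_sigma = 0.05,
                           inactive_sd = 0.2, amplitude_cv = 0.1, seed = 1) {
  marker_names <- names(baseline)
  baseline <- as.numeric(baseline)
  if (any(baseline <= 0)) stop("baseline intensities must be positive")
  p <- length(baseline)
  if (is.null(marker_names)) marker_names <- paste0("marker_", seq_len(p))
  processes <- as.matrix(processes)
  if (nrow(processes) != p)
    stop("processes must have one row per marker")
  processes <- sweep(processes, 2L, sqrt(colSums(processes^2)), "/")
  P <- ncol(processes)
  if (is.null(colnames(processes)))
    colnames(processes) <- paste0("P", seq_len(P))

  sp <- as.data.frame(subpopulations)
  if (!all(c("name", "barcode") %in% names(sp)))
    stop("subpopulations needs 'name' and 'barcode' columns")
  if (any(nchar(sp$barcode) != P))
    stop("barcodes must have one character per planted process (", P, ")")
  if (any(!strsplit(paste(sp$barcode, collapse = ""), "")[[1]] %in%
          c("+", "-", "0")))
    stop("barcode characters must be '+', '-' or '0'")
  conds <- names(n_cells)
  if (is.null(conds)) stop("n_cells must be a named vector of conditions")
  for (cc in conds) {
    if (!cc %in% names(sp)) stop("subpopulations lacks fraction column: ", cc)
    f <- sp[[cc]]
    if (any(f < 0) || sum(f) > 1 + 1e-9)
      stop("fractions for condition '", cc,
           "' must be nonnegative and sum to at most 1")
  }
  structure(list(baseline = stats::setNames(baseline, marker_names),
                 marker_names = marker_names, processes = processes,
                 subpopulations = sp, n_cells = n_cells,
                 amplitude = amplitude, noise_sigma = noise_sigma,
                 inactive_sd = inactive_sd, amplitude_cv = amplitude_cv,
                 seed = as.integer(seed)),
            class = "csss_synthspec")
}

#' Orthonormal planted process vectors
#'
#' Gram-Schmidt orthonormalizes target weight vectors against each other and
#' against the log-baseline direction, so planted processes occupy the
#' constraint subspace rather than tilting the reference term.
#'
#' @param targets n_markers x P matrix of desired (approximate) loadings.
#' @param baseline per-marker baseline intensities.
#' @return n_markers x P matrix with orthonormal columns, each also
#'   orthogonal to `log(baseline)`.
#' @export
orthogonal_processes <- function(targets, baseline) {
  targets <- as.matrix(targets)
  basis <- list(log(as.numeric(baseline)))
  basis[[1]] <- basis[[1]] / sqrt(sum(basis[[1]]^2))
  out <- matrix(0, nrow(targets), ncol(targets),
                dimnames = dimnames(targets))
  for (j in seq_len(ncol(targets))) {
    v <- targets[, j]
    for (b in basis) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10)
      stop("target vector ", j, " is collinear with the baseline/previous processes")
    v <- v / nv
    basis[[length(basis) + 1L]] <- v
    out[, j] <- v
  }
  out
}

# largest-remainder allocation of n cells to fractions (sum(frac) <= 1)
allocate_counts <- function(frac, n) {
  raw <- frac * n
  base <- floor(raw)
  left <- round(sum(raw)) - sum(base)
  if (left > 0) {
    add <- order(-(raw - base), seq_along(raw))[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate synthetic cells from a spec
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `csss_simulation`: list with `expression`
#'   (a pooled `csss_expression` over all conditions), `truth` (data.frame
#'   `cell_id`, `condition`, `subpop`, `barcode` of the planted signature),
#'   and `spec`.
#' @examples
#' sim <- generate_cells(rt_scenario_spec(seed = 7,
#'   n_cells = c(control = 500, RT_d6 = 500)))
#' table(sim$truth$subpop, sim$truth$condition)
#' @export
generate_cells <- function(spec) {
  stopifnot(inherits(spec, "csss_synthspec"))
  set.seed(spec$seed)
  Gp <- spec$processes
  P <- ncol(Gp)
  sp <- spec$subpopulations
  sign_of <- c("-" = -1L, "0" = 0L, "+" = 1L)
  bsign <- t(vapply(strsplit(sp$barcode, ""),
                    function(ch) unname(sign_of[ch]), integer(P)))
  if (P == 1L) bsign <- matrix(bsign, ncol = 1L)

  vals <- list(); ids <- list(); labs <- list(); truth <- list()
  for (cc in names(spec$n_cells)) {
    n <- as.integer(spec$n_cells[[cc]])
    cnt <- allocate_counts(sp[[cc]], n)
    n_ss <- n - sum(cnt)
    subpop <- c(rep(sp$name, cnt), rep("steady_state", n_ss))
    bc <- rbind(bsign[rep(seq_len(nrow(sp)), cnt), , drop = FALSE],
                matrix(0L, n_ss, P))
    lam <- matrix(rnorm(n * P, 0, spec$inactive_sd), n, P)
    act <- bc != 0L
    lam[act] <- bc[act] * spec$amplitude +
      rnorm(sum(act), 0, spec$amplitude_cv * spec$amplitude)
    logx <- matrix(log(spec$baseline), n, length(spec$baseline), byrow = TRUE) +
      tcrossprod(lam, Gp) +
      matrix(rnorm(n * length(spec$baseline), 0, spec$noise_sigma),
             n, length(spec$baseline))
    ord <- sample.int(n)
    vals[[cc]] <- exp(logx[ord, , drop = FALSE])
    ids[[cc]] <- sprintf("%s_%06d", cc, seq_len(n))
    labs[[cc]] <- rep(cc, n)
    truth[[cc]] <- data.frame(
      condition = cc, subpop = subpop[ord],
      barcode = barcode_strings(bc[ord, , drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- cbind(data.frame(cell_id = unlist(ids, use.names = FALSE),
                            stringsAsFactors = FALSE), truth)
  rownames(truth) <- NULL
  expr <- expression_matrix(do.call(rbind, vals),
                            marker_names = spec$marker_names,
                            cell_ids = truth$cell_id,
                            sample_labels = unlist(labs, use.names = FALSE))
  structure(list(expression = expr, truth = truth, spec = spec),
            class = "csss_simulation")
}

#' Radiotherapy-response study scenario
#'
#' The default study conditions: an 11-marker surface-oncomarker panel, four
#' planted unbalanced processes and eight planted subpopulations above the
#' 1 percent dominance floor in at least one condition, ~30,000 cells per condition
#' (control and day-6 post-radiotherapy). The planted mixing fractions
#' include a subpopulation carrying only process 3 (Her2/EGFR-driven) that
#' expands 0.3 to 21 percent (70-fold), one carrying only process 4
#' (cMet/MUC1-driven, E-cadherin down) emerging from undetectable to 1.5 percent,
#' and one contracting 9.9 to 4.9 percent.
#'
#' Every planted subpopulation carries exactly one process, and each process
#' has carriers on both amplitude signs in roughly balancing proportions.
#' This keeps the planted amplitudes uncorrelated across cells with near-zero
#' means, which is what makes the planted weight vectors recoverable by the
#' eigendecomposition: correlated or strongly one-sided factors would be
#' identifiable only up to a rotation.
#'
#' @param seed integer seed.
#' @param n_cells named vector of cells per condition.
#' @param noise_sigma log-scale noise SD (default 0.05).
#' @param amplitude active amplitude magnitude (default 3).
#' @param inactive_sd inactive-process jitter SD (default 0.2).
#' @return A `csss_synthspec`.
#' @export
rt_scenario_spec <- function(seed = 1,
                             n_cells = c(control = 30000, RT_d6 = 30000),
                             noise_sigma = 0.05, amplitude = 3,
                             inactive_sd = 0.2) {
  markers <- c("Her2", "EGFR", "cMet", "MUC1", "ECad", "EpCAM",
               "CD44", "CD24", "PDL1", "AXL", "Vim")
  baseline <- stats::setNames(
    c(120, 340, 260, 180, 900, 450, 700, 150, 80, 60, 200), markers)
  tg <- matrix(0, 11, 4, dimnames = list(markers, paste0("P", 1:4)))
  tg["CD44", 1] <- 0.6; tg["CD24", 1] <- -0.5
  tg["EpCAM", 1] <- 0.4; tg["Vim", 1] <- 0.3          # stemness-like axis
  tg["PDL1", 2] <- 0.6; tg["AXL", 2] <- 0.55
  tg["EGFR", 2] <- 0.3                                 # immune-evasion axis
  tg["Her2", 3] <- 0.75; tg["EGFR", 3] <- 0.5          # Her2/EGFR co-induction
  tg["cMet", 4] <- 0.6; tg["MUC1", 4] <- 0.5
  tg["ECad", 4] <- -0.45                               # cMet/MUC1 up, ECad down
  procs <- orthogonal_processes(tg[, c(3, 4, 1, 2)], baseline)[, c(3, 4, 1, 2)]

  sub <- data.frame(
    name    = c("a", "b", "c", "d", "e", "f", "g", "h"),
    barcode = c("+000", "00+0", "0+00", "-000", "0-00", "000+", "00-0", "000-"),
    control = c(0.170, 0.003, 0.099, 0.150, 0.120, 0.000, 0.020, 0.030),
    RT_d6   = c(0.150, 0.210, 0.049, 0.140, 0.100, 0.015, 0.012, 0.020),
    stringsAsFactors = FALSE)
  names(sub)[3:4] <- names(n_cells)

  synthetic_spec(baseline = baseline, processes = procs,
                 subpopulations = sub, n_cells = n_cells,
                 amplitude = amplitude, noise_sigma = noise_sigma,
                 inactive_sd = inactive_sd, seed = seed)
}

#' Match fitted processes to planted ones
#'
#' Greedily pairs each planted process with the fitted constraint column of
#' maximum absolute cosine similarity (distinct fitted columns), recording
#' the sign of the match.
#'
#' @param dec a `csss_decomposition` fitted to generated data.
#' @param spec the `csss_synthspec` that generated it (or a planted
#'   weight-vector matrix).
#' @return data.frame: `planted` (column name), `fitted_process` (index
#'   alpha), `cosine` (signed), `abs_cosine`.
#' @export
match_planted_processes <- function(dec, spec) {
  stopifnot(inherits(dec, "csss_decomposition"))
  Gp <- if (inherits(spec, "csss_synthspec")) spec$processes else as.matrix(spec)
  Gf <- dec$G[, -1L, drop = FALSE]
  cosm <- crossprod(Gf, Gp)     # fitted x planted; columns unit norm
  P <- ncol(Gp)
  fitted_idx <- integer(P); cosv <- numeric(P)
  taken <- rep(FALSE, ncol(Gf))
  for (j in order(-apply(abs(cosm), 2L, max))) {
    cj <- abs(cosm[, j]); cj[taken] <- -Inf
    i <- which.max(cj)
    taken[i] <- TRUE
    fitted_idx[j] <- i
    cosv[j] <- cosm[i, j]
  }
  data.frame(planted = colnames(Gp), fitted_process = fitted_idx,
             cosine = cosv, abs_cosine = abs(cosv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Translate planted barcodes into fitted-process barcodes
#'
#' Re-expresses a planted barcode string (over the generator's P processes)
#' on the fitted decomposition's K processes, using a
#' [match_planted_processes()] mapping: matched positions take the planted
#' sign times the sign of the cosine, all other positions are 0.
#'
#' @param barcodes character vector of planted barcode strings.
#' @param mapping result of [match_planted_processes()].
#' @param K number of fitted constraint processes.
#' @return character vector of fitted-space barcode strings.
#' @export
translate_barcodes <- function(barcodes, mapping, K) {
  sign_of <- c("-" = -1L, "0" = 0L, "+" = 1L)
  uniq <- unique(barcodes)
  out <- vapply(uniq, function(b) {
    s <- unname(sign_of[strsplit(b, "")[[1]]])
    v <- integer(K)
    v[mapping$fitted_process] <- s * sign(mapping$cosine)
    barcode_strings(matrix(v, nrow = 1))
  }, character(1))
  unname(out[match(barcodes, uniq)])
}
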