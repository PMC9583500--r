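#' Per-process amplitude thresholds from the sorted-amplitude curve
#'
#' Determines, for every unbalanced process, the lower/upper amplitude
#' cutoffs such that only cells on the tails of the sorted ("sigmoid")
#' \eqn{\lambda_\alpha(cell)} distribution count the process as active.
#' Thresholds are computed once on the pooled population (all conditions
#' together) so that condition comparisons use a common ruler.
#'
#' Two methods are available:
#' \describe{
#' \item{`knee`}{(default) Emulates reading the tails off the sorted sigmoid
#'   curve. Each half of the sorted curve (median outward) is examined with
#'   the max-distance-to-chord rule; the cut is initialized at the first
#'   prominent local maximum of the chord distance moving outward from the
#'   median (prominence 0.75 of the global maximum) and refined by a
#'   one-dimensional two-means step. A side is accepted as a genuine tail
#'   only if the cells beyond the cut form a cluster well separated from the
#'   body: `(median(tail) - median(body)) / (IQR(body)/1.349) >=
#'   min_separation`. Sides failing the gate get no active cells (cut at the
#'   extreme value); without this gate a plain Gaussian amplitude column
#'   would always "donate" its smooth 5-15% quantile shoulder as a fake
#'   tail. Near-linear halves (normalized chord distance < `lin_tol`) are
#'   degenerate and fall back to the quantile rule with a warning.}
#' \item{`quantile`}{Reproducible fallback: cuts at the `tail_fraction` and
#'   `1 - tail_fraction` empirical quantiles.}
#' }
#'
#' A cell is active (two-sided) when its amplitude is strictly outside
#' `[lower_cut, upper_cut]`; the lower tail is "active, negative sense".
#' The central interval always retains at least 50 percent of cells (cuts are
#' widened to the quartiles if ever necessary).
#'
#' @param x a `csss_decomposition`, or a numeric matrix/vector of amplitudes
#'   (columns = processes).
#' @param method `"knee"` or `"quantile"`.
#' @param tail_fraction quantile-method tail mass per side, in (0, 0.25].
#' @param min_separation knee-method cluster-separation gate (default 4);
#'   calibrated so that Gaussian, Student-t and moderately skewed unimodal
#'   columns (robust separation about 2.5-3.4) are rejected while planted
#'   carrier clusters 3 noise-SDs out (4.4 and up) are accepted.
#' @param lin_tol normalized chord-distance floor below which a half-curve is
#'   treated as linear/degenerate (default 0.05).
#'
#' @return A data.frame of class `csss_thresholds` with one row per process:
#'   `process`, `lower_cut`, `upper_cut`, `method`, `param`, `active_low`,
#'   `active_high` (realized active-cell fractions per side).
#' @examples
#' lam <- cbind(p1 = c(rnorm(900), rnorm(100, 5, 0.3)))
#' compute_thresholds(lam, method = "quantile", tail_fraction = 0.05)
#' @export
compute_thresholds <- function(x, method = c("knee", "quantile"),
                               tail_fraction = 0.05, min_separation = 4,
                               lin_tol = 0.05) {
  method <- match.arg(method)
  if (inherits(x, "csss_decomposition")) {
    if (x$K < 1) stop("decomposition has no constraint processes (K = 0)")
    lam <- x$Lambda[, -1L, drop = FALSE]
  } else {
    lam <- as.matrix(x)
  }
  if (!is.numeric(lam)) stop("amplitudes must be numeric")
  if (method == "quantile" &&
      (tail_fraction <= 0 || tail_fraction > 0.25))
    stop("tail_fraction must be in (0, 0.25]")

  K <- ncol(lam)
  res <- vector("list", K)
  for (a in seq_len(K)) {
    v <- lam[, a]
    if (diff(range(v)) == 0) {           # constant column: no cell active
      cuts <- c(v[1L], v[1L])
      meth <- method
    } else if (method == "quantile") {
      cuts <- unname(quantile(v, c(tail_fraction, 1 - tail_fraction)))
      meth <- "quantile"
    } else {
      kn <- knee_cuts(v, min_separation = min_separation, lin_tol = lin_tol,
                      tail_fraction = tail_fraction)
      if (kn$degenerate)
        warning("process ", a, ": degenerate (near-linear) sorted-amplitude ",
                "curve; falling back to quantile cuts")
      cuts <- kn$cuts
      meth <- kn$method
    }
    # invariant: central interval keeps >= 50% of cells
    if (mean(v >= cuts[1L] & v <= cuts[2L]) < 0.5) {
      q <- unname(quantile(v, c(0.25, 0.75)))
      cuts <- c(min(cuts[1L], q[1L]), max(cuts[2L], q[2L]))
    }
    res[[a]] <- data.frame(
      process = a, lower_cut = cuts[1L], upper_cut = cuts[2L], method = meth,
      param = if (meth == "quantile") tail_fraction else min_separation,
      active_low = mean(v < cuts[1L]), active_high = mean(v > cuts[2L]))
  }
  out <- do.call(rbind, res)
  class(out) <- c("csss_thresholds", "data.frame")
  attr(out, "pooled_n") <- nrow(lam)
  out
}

# Two-sided knee cuts on one amplitude column. Returns cuts (lower, upper),
# the method actually used per the degenerate fallback, and a degenerate flag.
knee_cuts <- function(v, min_separation, lin_tol, tail_fraction) {
  s <- sort(v)
  n <- length(s)
  m <- ceiling(n / 2)
  up <- knee_side(s[m:n], min_separation, lin_tol)
  lo <- knee_side(-s[m:1], min_separation, lin_tol)
  degenerate <- up$degenerate || lo$degenerate
  if (degenerate) {
    q <- unname(quantile(v, c(tail_fraction, 1 - tail_fraction)))
    lower <- if (lo$degenerate) q[1L] else -lo$cut
    upper <- if (up$degenerate) q[2L] else up$cut
    method <- "knee+quantile_fallback"
  } else {
    lower <- -lo$cut
    upper <- up$cut
    method <- "knee"
  }
  list(cuts = c(lower, upper), method = method, degenerate = degenerate)
}

# One side of the sorted curve, oriented increasing away from the center
# (h[1] ~ median). Returns the cut value; cells strictly beyond the cut are
# active. cut = max(h) encodes "no tail on this side".
knee_side <- function(h, min_separation, lin_tol, grid = 512L, prominence = 0.75) {
  n <- length(h)
  if (n < 8L || h[n] == h[1L])
    return(list(cut = h[n], degenerate = FALSE, separation = NA_real_))
  idx <- unique(round(seq(1L, n, length.out = min(grid, n))))
  x <- (idx - 1) / (n - 1)
  y <- (h[idx] - h[1L]) / (h[n] - h[1L])
  d <- (x - y) / sqrt(2)                 # >0 where the curve sags below the chord
  if (max(d) < lin_tol)
    return(list(cut = h[n], degenerate = TRUE, separation = NA_real_))
  k <- length(d)
  locmax <- which(d >= c(-Inf, d[-k]) & d >= c(d[-1L], -Inf) & d > 0)
  locmax <- locmax[d[locmax] >= prominence * max(d)]
  cut <- h[idx[locmax[1L]]]
  for (it in 1:50) {                     # 1-D two-means refinement
    tail_m <- h > cut
    if (!any(tail_m) || all(tail_m)) break
    newcut <- (mean(h[tail_m]) + mean(h[!tail_m])) / 2
    if (abs(newcut - cut) < 1e-12) break
    cut <- newcut
  }
  A <- h[h > cut]
  B <- h[h <= cut]
  sep <- if (length(A) < 2L || length(B) < 2L) Inf else {
    s_B <- IQR(B) / 1.349
    if (s_B <= 0) s_B <- max(sd(B), .Machine$double.eps)
    (median(A) - median(B)) / s_B
  }
  if (sep < min_separation) cut <- h[n]  # no genuine tail on this side
  list(cut = cut, degenerate = FALSE, separation = sep)
}

#' Write a threshold table as delimited text
#' @param thr a `csss_thresholds` table.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thr, path) {
  stopifnot(inherits(thr, "csss_thresholds"))
  data.table::fwrite(as.data.frame(thr), path, sep = "\t")
  invisible(path)
}
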