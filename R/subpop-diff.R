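#' Compare subpopulation abundances between two conditions
#'
#' For every barcode, computes the fold change of the treated fraction over
#' the control fraction, the absolute change, and a two-sided two-proportion
#' z-test p-value (descriptive; Benjamini-Hochberg adjusted values reported
#' alongside). When the control fraction is below `detection_floor` the
#' barcode is undetectable at baseline: the fold change is then reported as
#' the conservative lower bound `treated_frac / detection_floor` with
#' `fold_is_bound = TRUE`, never as infinity, and the `emergent` flag is set
#' when the treated fraction also clears the table's abundance floor.
#'
#' When per-replicate subpopulation tables are supplied (e.g. one table per
#' flask/experiment), the p-value is instead a two-sample Student t-test on
#' the per-replicate fractions.
#'
#' @param tab a `csss_subpops` table containing both conditions.
#' @param control_label,treated_label condition labels present in `tab`.
#' @param detection_floor fraction below which a subpopulation counts as
#'   undetectable; default `1 / n_cells(control)` (i.e. zero observed cells).
#' @param replicate_tables optional list of `csss_subpops` tables, one per
#'   replicate, each containing both conditions.
#' @return A data.frame of class `csss_diff`: `barcode`, `label`,
#'   `control_count`, `treated_count`, `control_frac`, `treated_frac`,
#'   `fold_change`, `fold_is_bound`, `abs_change`, `emergent`, `p_value`,
#'   `p_adj`.
#' @export
compare_conditions <- function(tab, control_label, treated_label,
                               detection_floor = NULL,
                               replicate_tables = NULL) {
  stopifnot(inherits(tab, "csss_subpops"))
  if (identical(control_label, treated_label))
    stop("control and treated labels must differ")
  n_by <- attr(tab, "n_cells")
  for (lab in c(control_label, treated_label)) {
    if (!lab %in% names(n_by))
      stop("condition not in table: ", lab)
  }
  nc <- n_by[[control_label]]
  nt <- n_by[[treated_label]]
  if (is.null(detection_floor)) detection_floor <- 1 / nc
  floor_ab <- attr(tab, "abundance_floor")

  xc <- tab[[paste0("count_", control_label)]]
  xt <- tab[[paste0("count_", treated_label)]]
  cf <- xc / nc
  tf <- xt / nt

  detectable <- cf >= detection_floor
  fold <- ifelse(detectable, tf / cf, tf / detection_floor)
  fold[!detectable & tf == 0] <- NA_real_   # absent in both: no fold change
  emergent <- !detectable & tf >= floor_ab

  pv <- if (is.null(replicate_tables)) {
    vapply(seq_along(xc), function(i) {
      if (xc[i] + xt[i] == 0L) return(NA_real_)
      suppressWarnings(
        prop.test(c(xc[i], xt[i]), c(nc, nt), correct = FALSE)$p.value)
    }, numeric(1))
  } else {
    rep_frac <- function(rt, lab) {
      n_rt <- attr(rt, "n_cells")[[lab]]
      f <- rt[[paste0("count_", lab)]][match(tab$barcode, rt$barcode)] / n_rt
      f[is.na(f)] <- 0
      f
    }
    fc <- vapply(replicate_tables, rep_frac, numeric(nrow(tab)), control_label)
    ft <- vapply(replicate_tables, rep_frac, numeric(nrow(tab)), treated_label)
    vapply(seq_len(nrow(tab)), function(i) {
      a <- fc[i, ]; b <- ft[i, ]
      if (var(a) + var(b) == 0) return(NA_real_)
      t.test(b, a)$p.value
    }, numeric(1))
  }

  out <- data.frame(barcode = tab$barcode, label = tab$label,
                    control_count = xc, treated_count = xt,
                    control_frac = cf, treated_frac = tf,
                    fold_change = fold, fold_is_bound = !detectable & tf > 0,
                    abs_change = tf - cf, emergent = emergent,
                    p_value = pv, p_adj = p.adjust(pv, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("csss_diff", "data.frame")
  attr(out, "control") <- control_label
  attr(out, "treated") <- treated_label
  attr(out, "detection_floor") <- detection_floor
  out
}

#' Write a differential abundance report as delimited text
#' @param rep a `csss_diff` report.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_differential <- function(rep, path) {
  stopifnot(inherits(rep, "csss_diff"))
  data.table::fwrite(as.data.frame(rep), path, sep = "\t")
  invisible(path)
}
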