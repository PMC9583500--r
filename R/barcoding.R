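#' Assign CSSS barcodes to cells
#'
#' Converts each cell's set of significantly active processes (its
#' cell-specific signaling signature, CSSS) into a barcode. Position
#' \eqn{\alpha} of a cell's barcode is +1 when
#' \eqn{\lambda_\alpha(cell) >} `upper_cut`, -1 when below `lower_cut`,
#' and 0 otherwise. In `signed` mode (default) the sign is kept, so
#' subpopulations with a process induced versus repressed are distinct
#' phenotypes; `binary` mode records mere activity (`abs` of the signed
#' barcode), reproducing the active/inactive barcode graphic.
#'
#' @param dec a `csss_decomposition`.
#' @param thr a `csss_thresholds` table for the same process set.
#' @param mode `"signed"` or `"binary"`.
#' @return An object of class `csss_barcodes`: list with `barcodes`
#'   (n_cells x K integer matrix), `strings` (barcode rendered as a
#'   +/-/0 string, e.g. `"00+0000000"`), `mode`, `cell_ids`,
#'   `sample_labels`, `K`.
#' @export
assign_barcodes <- function(dec, thr, mode = c("signed", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dec, "csss_decomposition"),
            inherits(thr, "csss_thresholds"))
  if (nrow(thr) != dec$K)
    stop("threshold table has ", nrow(thr), " processes but decomposition has K = ",
         dec$K)
  lam <- dec$Lambda[, -1L, drop = FALSE]
  B <- matrix(0L, nrow = nrow(lam), ncol = dec$K)
  for (a in seq_len(dec$K)) {
    B[lam[, a] > thr$upper_cut[a], a] <- 1L
    B[lam[, a] < thr$lower_cut[a], a] <- -1L
  }
  if (mode == "binary") B <- abs(B)
  colnames(B) <- paste0("process_", seq_len(dec$K))
  structure(list(barcodes = B, strings = barcode_strings(B), mode = mode,
                 cell_ids = dec$cell_ids, sample_labels = dec$sample_labels,
                 K = dec$K),
            class = "csss_barcodes")
}

# render a ternary barcode matrix as +/-/0 strings, one per row
barcode_strings <- function(B) {
  chars <- c("-", "0", "+")
  cols <- lapply(seq_len(ncol(B)), function(j) chars[B[, j] + 2L])
  do.call(paste0, cols)
}

#' @export
print.csss_barcodes <- function(x, ...) {
  cat("<csss_barcodes> ", length(x$strings), " cells, K = ", x$K,
      " processes, mode = ", x$mode, "\n", sep = "")
  cat("  distinct barcodes: ", length(unique(x$strings)), "; all-zero: ",
      sprintf("%.1f%%", 100 * mean(x$strings == strrep("0", x$K))),
      "\n", sep = "")
  invisible(x)
}

# spreadsheet-style lowercase letter sequence: a..z, aa, ab, ...
letter_labels <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    v <- i
    s <- ""
    while (v > 0) {
      r <- (v - 1) %% 26
      s <- paste0(letters[r + 1], s)
      v <- (v - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

#' Tabulate barcode-defined subpopulations per condition
#'
#' Groups cells by barcode and counts them per condition. Letter labels
#' (a, b, c, ... by descending pooled abundance, ties broken lexicographically
#' by barcode string) name the process-active barcodes; the all-zero barcode
#' is the steady-state bulk, labeled `"ss"`, and is never flagged dominant.
#' Rare barcodes are retained in the table, merely unflagged.
#'
#' @param bars a `csss_barcodes`.
#' @param abundance_floor dominance floor on the within-condition fraction,
#'   default 0.01 (the "over 1 percent of cells" rule).
#' @param floor_scope `"any_condition"` (default; flags subpopulations that
#'   emerge only after treatment) or `"pooled"`.
#' @param conditions optional character vector of condition labels to
#'   tabulate (default: all, in order of first appearance). A requested
#'   condition with no cells is an error.
#' @return A data.frame of class `csss_subpops`: `barcode`, `label`,
#'   `dominant`, per condition `count_<cond>` and `frac_<cond>`, plus
#'   `pooled_count`, `pooled_frac`. Attributes `n_cells` (named per
#'   condition), `abundance_floor`, `floor_scope`, `mode`.
#' @export
tabulate_subpopulations <- function(bars, abundance_floor = 0.01,
                                    floor_scope = c("any_condition", "pooled"),
                                    conditions = NULL) {
  floor_scope <- match.arg(floor_scope)
  stopifnot(inherits(bars, "csss_barcodes"))
  if (abundance_floor < 0 || abundance_floor >= 1)
    stop("abundance_floor must be in [0, 1)")
  if (is.null(conditions)) conditions <- unique(bars$sample_labels)
  n_by <- vapply(conditions, function(cc) sum(bars$sample_labels == cc),
                 integer(1))
  if (any(n_by == 0L))
    stop("empty condition: ",
         paste(conditions[n_by == 0L], collapse = ", "))
  keep <- bars$sample_labels %in% conditions
  tab <- table(barcode = bars$strings[keep],
               condition = factor(bars$sample_labels[keep],
                                  levels = conditions))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  pooled <- rowSums(counts)
  ord <- order(-pooled, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  pooled <- pooled[ord]

  fracs <- sweep(counts, 2L, n_by, "/")
  zero <- strrep("0", bars$K)
  is_null <- rownames(counts) == zero
  labels <- character(nrow(counts))
  labels[!is_null] <- letter_labels(sum(!is_null))
  labels[is_null] <- "ss"
  dominant <- if (floor_scope == "any_condition") {
    apply(fracs, 1L, function(f) any(f >= abundance_floor))
  } else {
    pooled / sum(n_by) >= abundance_floor
  }
  dominant[is_null] <- FALSE

  out <- data.frame(barcode = rownames(counts), label = labels,
                    dominant = dominant, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (cc in conditions) {
    out[[paste0("count_", cc)]] <- counts[, cc]
    out[[paste0("frac_", cc)]] <- fracs[, cc]
  }
  out$pooled_count <- as.integer(pooled)
  out$pooled_frac <- pooled / sum(n_by)
  class(out) <- c("csss_subpops", "data.frame")
  attr(out, "n_cells") <- n_by
  attr(out, "abundance_floor") <- abundance_floor
  attr(out, "floor_scope") <- floor_scope
  attr(out, "mode") <- bars$mode
  out
}

#' Write barcodes / subpopulation tables as delimited text
#' @param bars a `csss_barcodes`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(bars, path) {
  stopifnot(inherits(bars, "csss_barcodes"))
  data.table::fwrite(
    data.table::data.table(cell_id = bars$cell_ids,
                           condition = bars$sample_labels,
                           barcode = bars$strings),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_barcodes
#' @param tab a `csss_subpops` table.
#' @export
write_subpopulations <- function(tab, path) {
  stopifnot(inherits(tab, "csss_subpops"))
  data.table::fwrite(as.data.frame(tab), path, sep = "\t")
  invisible(path)
}
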