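#' Run the full CSSS pipeline
#'
#' Chains the analysis stages — decomposition, amplitude thresholds, barcode
#' assignment, subpopulation tabulation and (with two or more conditions)
#' differential abundance — and writes every artifact plus a manifest of all
#' realized parameters to `out_dir`. The analysis stages are deterministic:
#' re-running with the same config and inputs gives byte-identical tables.
#'
#' @param input a `csss_expression`, a `csss_simulation`, or a path readable
#'   by [read_expression()].
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param offset positive constant added before the log (default 1).
#' @param max_processes optional cap on constraint processes.
#' @param threshold_method,tail_fraction,min_separation see
#'   [compute_thresholds()].
#' @param barcode_mode `"signed"` or `"binary"`, see [assign_barcodes()].
#' @param abundance_floor,floor_scope see [tabulate_subpopulations()].
#' @param control_label,treated_label condition labels for the differential
#'   report; default: first and second condition in order of appearance.
#'   Ignored when only one condition is present.
#' @param detection_floor see [compare_conditions()].
#' @return An object of class `csss_run`: list with `expression`,
#'   `decomposition`, `thresholds`, `barcodes`, `subpopulations`,
#'   `differential` (or `NULL`), `config`, `out_dir`.
#' @examples
#' sim <- generate_cells(rt_scenario_spec(seed = 1,
#'   n_cells = c(control = 1000, RT_d6 = 1000)))
#' run <- run_pipeline(sim, out_dir = NULL)
#' subset(run$subpopulations, dominant)
#' @export
run_pipeline <- function(input, out_dir = NULL, offset = 1,
                         max_processes = NULL,
                         threshold_method = c("knee", "quantile"),
                         tail_fraction = 0.05, min_separation = 4,
                         barcode_mode = c("signed", "binary"),
                         abundance_floor = 0.01,
                         floor_scope = c("any_condition", "pooled"),
                         control_label = NULL, treated_label = NULL,
                         detection_floor = NULL) {
  threshold_method <- match.arg(threshold_method)
  barcode_mode <- match.arg(barcode_mode)
  floor_scope <- match.arg(floor_scope)

  x <- if (inherits(input, "csss_simulation")) input$expression
       else if (inherits(input, "csss_expression")) input
       else if (is.character(input)) read_expression(input)
       else stop("input must be an expression matrix, simulation, or file path")

  stage <- "fit_surprisal"
  res <- tryCatch({
    dec <- fit_surprisal(x, offset = offset, max_processes = max_processes)
    stage <- "compute_thresholds"
    thr <- compute_thresholds(dec, method = threshold_method,
                              tail_fraction = tail_fraction,
                              min_separation = min_separation)
    stage <- "assign_barcodes"
    bars <- assign_barcodes(dec, thr, mode = barcode_mode)
    stage <- "tabulate_subpopulations"
    tab <- tabulate_subpopulations(bars, abundance_floor = abundance_floor,
                                   floor_scope = floor_scope)
    diffrep <- NULL
    conds <- unique(x$sample_labels)
    if (length(conds) >= 2L) {
      stage <- "compare_conditions"
      if (is.null(control_label)) control_label <- conds[1L]
      if (is.null(treated_label)) treated_label <- conds[2L]
      diffrep <- compare_conditions(tab, control_label, treated_label,
                                    detection_floor = detection_floor)
    }
    list(decomposition = dec, thresholds = thr, barcodes = bars,
         subpopulations = tab, differential = diffrep)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  config <- list(offset = offset, max_processes = max_processes,
                 threshold_method = threshold_method,
                 tail_fraction = tail_fraction,
                 min_separation = min_separation,
                 barcode_mode = barcode_mode,
                 abundance_floor = abundance_floor,
                 floor_scope = floor_scope,
                 control_label = control_label,
                 treated_label = treated_label,
                 detection_floor = detection_floor)
  out <- structure(c(list(expression = x), res,
                     list(config = config, out_dir = out_dir)),
                   class = "csss_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# write every artifact + a manifest of realized parameters
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_decomposition(run$decomposition, out_dir)
  write_thresholds(run$thresholds, file.path(out_dir, "thresholds.tsv"))
  write_barcodes(run$barcodes, file.path(out_dir, "barcodes.tsv"))
  write_subpopulations(run$subpopulations,
                       file.path(out_dir, "subpopulations.tsv"))
  if (!is.null(run$differential))
    write_differential(run$differential, file.path(out_dir, "differential.tsv"))
  n_by <- attr(run$subpopulations, "n_cells")
  manifest <- c(run$config, list(
    n_cells = as.list(n_by),
    n_markers = length(run$decomposition$marker_names),
    marker_names = run$decomposition$marker_names,
    K = run$decomposition$K,
    importance = run$decomposition$importance,
    realized_active_low = run$thresholds$active_low,
    realized_active_high = run$thresholds$active_high,
    csss_version = as.character(utils::packageVersion("csss"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.csss_run <- function(x, ...) {
  cat("<csss_run>\n")
  print(x$expression)
  print(x$decomposition)
  cat("  dominant subpopulations: ",
      sum(x$subpopulations$dominant), "\n", sep = "")
  invisible(x)
}

#' PCA baseline embedding
#'
#' Thin, non-contractual comparison utility: principal components of the
#' log-intensities, for contrasting variance-driven embeddings with
#' CSSS-based subpopulation calls.
#'
#' @param x a `csss_expression`.
#' @param n_components number of components to return (default 2).
#' @param offset log offset (default 1).
#' @return data.frame with `cell_id`, `condition` and `PC1..PCn`.
#' @export
baseline_pca <- function(x, n_components = 2, offset = 1) {
  stopifnot(inherits(x, "csss_expression"))
  pc <- prcomp(log(x$values + offset), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- data.frame(cell_id = x$cell_ids, condition = x$sample_labels,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pc$x[, seq_len(k), drop = FALSE]))
}
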