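#' Single-cell expression matrix
#'
#' Container for a cells-by-markers matrix of nonnegative fluorescence
#' intensities with per-cell condition labels. This is the input to
#' [fit_surprisal()].
#'
#' @param values numeric matrix, n_cells x n_markers, nonnegative and finite.
#' @param marker_names character vector of unique marker names; defaults to
#'   `colnames(values)`.
#' @param cell_ids character vector of cell identifiers; defaults to
#'   `cell_1 ... cell_n`.
#' @param sample_labels per-cell condition/timepoint tag (e.g. `"control"`,
#'   `"RT_d6"`); a scalar is recycled.
#'
#' @return An object of class `csss_expression`: a list with elements
#'   `values`, `marker_names`, `cell_ids`, `sample_labels`.
#' @examples
#' x <- expression_matrix(matrix(c(10, 20, 30, 40, 50, 60), ncol = 2),
#'                        marker_names = c("Her2", "cMet"))
#' dim(x$values)
#' @export
expression_matrix <- function(values, marker_names = colnames(values),
                              cell_ids = NULL, sample_labels = "all") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(marker_names)) marker_names <- paste0("marker_", seq_len(p))
  marker_names <- as.character(marker_names)
  if (length(marker_names) != p)
    stop("marker_names length (", length(marker_names),
         ") does not match number of columns (", p, ")")
  if (anyDuplicated(marker_names))
    stop("marker_names must be unique; duplicated: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  if (p < 2) stop("at least 2 markers are required")
  if (n < p)
    stop("need n_cells >= n_markers for the covariance route (got ",
         n, " cells, ", p, " markers)")
  if (any(!is.finite(values))) stop("expression values must all be finite")
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) stop("cell_ids length does not match n_cells")
  if (length(sample_labels) == 1L) sample_labels <- rep(sample_labels, n)
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != n)
    stop("sample_labels must be a scalar or length n_cells")
  dimnames(values) <- list(NULL, marker_names)
  structure(list(values = values, marker_names = marker_names,
                 cell_ids = cell_ids, sample_labels = sample_labels),
            class = "csss_expression")
}

#' @export
print.csss_expression <- function(x, ...) {
  cat("<csss_expression> ", nrow(x$values), " cells x ", ncol(x$values),
      " markers\n", sep = "")
  cat("  markers:   ", paste(x$marker_names, collapse = ", "), "\n", sep = "")
  tab <- table(x$sample_labels)
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.csss_expression <- function(x) dim(x$values)

# restrict columns to a subset, in subset order
subset_markers <- function(x, marker_subset) {
  miss <- setdiff(marker_subset, x$marker_names)
  if (length(miss))
    stop("unknown marker(s) in subset: ", paste(miss, collapse = ", "))
  idx <- match(marker_subset, x$marker_names)
  expression_matrix(x$values[, idx, drop = FALSE],
                    marker_names = marker_subset,
                    cell_ids = x$cell_ids, sample_labels = x$sample_labels)
}

#' Read a single-cell expression matrix
#'
#' Reads a delimited table (comma or tab separated, auto-detected, one header
#' row of marker names) or an FCS 3.0/3.1 file into a [expression_matrix()].
#' A leading non-numeric column in a delimited file is taken as cell
#' identifiers; a column named `condition` is taken as per-cell sample
#' labels. Negative intensities (e.g. post-compensation FCS values) are
#' clipped to 0 at read time with a message, so that the log transform in
#' [fit_surprisal()] is well defined.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"delimited"` or `"fcs"`.
#' @param marker_subset optional character vector; the returned matrix is
#'   restricted to these markers, in this order.
#' @param channel_map for FCS input, a named character vector mapping channel
#'   names (`$PnN`) to marker names, e.g. `c("FL1-A" = "Her2")`. Unmapped
#'   channels keep their channel name.
#' @param sample_label condition label applied to all cells; defaults to the
#'   file name without extension. Ignored when the file carries a
#'   `condition` column.
#' @param clip_negative clip negative values to 0 (default `TRUE`).
#'
#' @return A `csss_expression` object preserving the cell order of the file.
#' @seealso [write_expression()], [concat_conditions()]
#' @export
read_expression <- function(path, format = c("auto", "delimited", "fcs"),
                            marker_subset = NULL, channel_map = NULL,
                            sample_label = NULL, clip_negative = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  }
  if (is.null(sample_label))
    sample_label <- sub("\\.[^.]*$", "", basename(path))
  raw <- if (format == "fcs") {
    read_fcs_matrix(path, channel_map = channel_map, sample_label = sample_label)
  } else {
    read_delimited_matrix(path, sample_label = sample_label)
  }
  if (any(raw$values < 0)) {
    if (!clip_negative)
      stop("negative intensities present and clip_negative = FALSE")
    nneg <- sum(raw$values < 0)
    message("clipping ", nneg, " negative intensit",
            if (nneg == 1) "y" else "ies", " to 0")
    raw$values[raw$values < 0] <- 0
  }
  x <- expression_matrix(raw$values, marker_names = raw$marker_names,
                         cell_ids = raw$cell_ids,
                         sample_labels = raw$sample_labels)
  if (!is.null(marker_subset)) x <- subset_markers(x, marker_subset)
  x
}

read_delimited_matrix <- function(path, sample_label) {
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE,
                          colClasses = NULL, showProgress = FALSE)
  if (!nrow(dt)) stop("no data rows in ", path)
  cols <- names(dt)
  cell_ids <- NULL
  if (!is.numeric(dt[[1L]])) {  # leading cell-id column
    cell_ids <- as.character(dt[[1L]])
    dt <- dt[, -1L]
    cols <- names(dt)
  }
  labels <- sample_label
  cond_col <- which(tolower(cols) == "condition")
  if (length(cond_col)) {
    labels <- as.character(dt[[cond_col[1L]]])
    dt <- dt[, -cond_col[1L], with = FALSE]
    cols <- names(dt)
  }
  for (j in seq_along(cols)) {
    v <- dt[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop("non-numeric entry in column '", cols[j], "', data row ", row,
           ": '", v[row], "'")
    }
  }
  list(values = as.matrix(dt), marker_names = cols,
       cell_ids = cell_ids, sample_labels = labels)
}

#' Write an expression matrix as delimited text
#'
#' Writes `cell_id`, marker columns and a `condition` column; the layout
#' round-trips through [read_expression()] at full double precision.
#'
#' @param x a `csss_expression`.
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "csss_expression"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # %.17g so doubles round-trip exactly through read_expression()
  dt <- data.table::as.data.table(
    apply(x$values, 2L, function(v) sprintf("%.17g", v)))
  dt <- cbind(data.table::data.table(cell_id = x$cell_ids), dt,
              data.table::data.table(condition = x$sample_labels))
  data.table::fwrite(dt, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Row-stack expression matrices from several conditions
#'
#' Pools e.g. control and post-treatment samples into one matrix for a joint
#' decomposition; per-cell sample labels are preserved per source.
#'
#' @param matrices a list of `csss_expression` objects with identical
#'   `marker_names` in identical order.
#' @return A pooled `csss_expression`.
#' @export
concat_conditions <- function(matrices) {
  if (inherits(matrices, "csss_expression")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "csss_expression")))
  ref <- matrices[[1L]]$marker_names
  for (i in seq_along(matrices)) {
    if (!identical(matrices[[i]]$marker_names, ref))
      stop("marker names of input ", i, " do not match input 1 ",
           "(identical names and order required)")
  }
  expression_matrix(
    do.call(rbind, lapply(matrices, `[[`, "values")),
    marker_names = ref,
    cell_ids = unlist(lapply(matrices, `[[`, "cell_ids"), use.names = FALSE),
    sample_labels = unlist(lapply(matrices, `[[`, "sample_labels"),
                           use.names = FALSE))
}
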