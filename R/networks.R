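#' Export one unbalanced process as a weighted, signed marker subnetwork
#'
#' The nodes are the markers participating significantly in process `alpha`
#' (`|G[i, alpha]| >= g_cut`), each carrying its weight and a direction. The
#' direction of marker i is the sign of the mean, over the chosen cell
#' subset, of the deviation product \eqn{G_{i\alpha}\lambda_\alpha(cell)}:
#' markers with positive amplitude and positive weight are upregulated by
#' the process in those cells. Optional interaction edges (pre-downloaded,
#' two-column identifier pairs) are filtered to pairs with both endpoints in
#' the node set; no live database lookups are performed.
#'
#' @param dec a `csss_decomposition`.
#' @param alpha process index, `1 <= alpha <= dec$K`.
#' @param bars a `csss_barcodes`; required for the `active_*` subsets.
#' @param g_cut nonnegative weight cutoff; default `1.96 / sqrt(n_markers)`
#'   (the weight a marker would need to stand out of a flat loading).
#' @param cell_subset cells over which directions are averaged:
#'   `"active_positive"` (barcode +1 on `alpha`), `"active_negative"`, or
#'   `"all"`.
#' @param edges optional two-column data.frame (`from`, `to`) of interaction
#'   pairs, e.g. from [read_edge_list()].
#' @return An object of class `csss_network`: list with `alpha`, `nodes`
#'   (data.frame `marker`, `weight`, `direction`), `edges`, `g_cut`,
#'   `cell_subset`, `n_cells_subset`.
#' @export
build_process_network <- function(dec, alpha, bars = NULL, g_cut = NULL,
                                  cell_subset = c("active_positive",
                                                  "active_negative", "all"),
                                  edges = NULL) {
  cell_subset <- match.arg(cell_subset)
  stopifnot(inherits(dec, "csss_decomposition"))
  if (alpha < 1 || alpha > dec$K)
    stop("alpha must be a process index in 1..K = ", dec$K)
  if (is.null(g_cut)) g_cut <- 1.96 / sqrt(length(dec$marker_names))
  if (g_cut < 0) stop("g_cut must be nonnegative")

  g <- dec$G[, alpha + 1L]
  sel <- abs(g) >= g_cut
  if (!any(sel))
    warning("no marker reaches |G| >= ", signif(g_cut, 3), " in process ",
            alpha, "; empty network")

  cells <- switch(cell_subset,
    all = rep(TRUE, nrow(dec$Lambda)),
    active_positive = ,
    active_negative = {
      if (is.null(bars))
        stop("bars is required for cell_subset = '", cell_subset, "'")
      want <- if (cell_subset == "active_positive") 1L else -1L
      bars$barcodes[, alpha] == want
    })
  mean_lam <- if (any(cells)) mean(dec$Lambda[cells, alpha + 1L]) else NA_real_
  dir_num <- sign(g[sel] * mean_lam)
  dir_num[is.na(dir_num)] <- 0
  nodes <- data.frame(marker = dec$marker_names[sel],
                      weight = unname(g[sel]),
                      direction = c("down", "none", "up")[dir_num + 2L],
                      row.names = NULL, stringsAsFactors = FALSE)
  ed <- data.frame(from = character(0), to = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(edges) && nrow(nodes)) {
    edges <- as.data.frame(edges)[, 1:2]
    names(edges) <- c("from", "to")
    keep <- edges$from %in% nodes$marker & edges$to %in% nodes$marker
    ed <- edges[keep, , drop = FALSE]
    rownames(ed) <- NULL
  }
  structure(list(alpha = as.integer(alpha), nodes = nodes, edges = ed,
                 g_cut = g_cut, cell_subset = cell_subset,
                 n_cells_subset = sum(cells)),
            class = "csss_network")
}

#' @export
print.csss_network <- function(x, ...) {
  cat("<csss_network> process ", x$alpha, ": ", nrow(x$nodes), " markers, ",
      nrow(x$edges), " edges (|G| >= ", signif(x$g_cut, 3), ", subset = ",
      x$cell_subset, ", n = ", x$n_cells_subset, ")\n", sep = "")
  if (nrow(x$nodes)) print(x$nodes)
  invisible(x)
}

#' Read a two-column interaction edge list
#'
#' Reads pre-downloaded interaction pairs (e.g. exported from a protein
#' interaction database) from a delimited file with two identifier columns.
#' A header row is detected and dropped when its first field is `from`
#' (case-insensitive).
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, select = 1:2,
                          showProgress = FALSE)
  names(dt) <- c("from", "to")
  if (nrow(dt) && tolower(dt$from[1L]) == "from") dt <- dt[-1L]
  as.data.frame(dt)
}

#' Write a process network as node-attribute and edge-list files
#'
#' Writes `<prefix>_nodes.tsv` (GraphML-compatible attribute names: `name`,
#' `weight`, `direction`) and `<prefix>_edges.tsv` (`source`, `target`).
#'
#' @param net a `csss_network`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_process_network <- function(net, prefix) {
  stopifnot(inherits(net, "csss_network"))
  npath <- paste0(prefix, "_nodes.tsv")
  epath <- paste0(prefix, "_edges.tsv")
  nodes <- net$nodes
  names(nodes)[names(nodes) == "marker"] <- "name"
  data.table::fwrite(nodes, npath, sep = "\t")
  edges <- net$edges
  names(edges) <- c("source", "target")
  data.table::fwrite(edges, epath, sep = "\t")
  invisible(c(npath, epath))
}
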