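#' Filter proteins by intensity ratio and significance
#'
#' Keeps proteins with `ratio >= ratio_cut` and `significance >= sig_cut`
#' (both inequalities inclusive). The defaults (2, 20) select strongly
#' up-regulated, well-supported proteins from a quantitative proteomics
#' ratio table.
#'
#' @param table Tibble/data frame with columns `protein`, `ratio`,
#'   `significance`.
#' @param ratio_cut Minimum intensity ratio; default 2.
#' @param sig_cut Minimum significance score; default 20.
#' @return Character vector of retained protein ids (warns when empty).
#' @export
filter_proteins <- function(table, ratio_cut = 2, sig_cut = 20) {
  stopifnot(all(c("protein", "ratio", "significance") %in% names(table)))
  keep <- table$ratio >= ratio_cut & table$significance >= sig_cut
  keep[is.na(keep)] <- FALSE
  out <- as.character(table$protein[keep])
  if (length(out) == 0L) {
    warning("no protein passes ratio >= ", ratio_cut,
            " and significance >= ", sig_cut)
  }
  out
}

#' Read a two-column edge list (optional score column)
#'
#' @param path TSV with columns `protein_a`, `protein_b` and an optional
#'   numeric score (e.g. a STRING combined score). A header line is detected
#'   when the last field of the first line is non-numeric for 3-column input
#'   or the line matches common column names.
#' @param min_score Optional score threshold; edges below it are dropped.
#' @return A tibble with columns `from`, `to` (and `score` when present).
#' @export
read_edge_list <- function(path, min_score = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short) > 0L) {
    stop("malformed edge at line ", idx[short[1L]],
         ": fewer than 2 tab-separated fields")
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  score <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, numeric(1))
  # drop a header line, if any
  if (length(from) > 0L &&
      tolower(from[1L]) %in% c("protein_a", "from", "node1", "source")) {
    from <- from[-1L]; to <- to[-1L]; score <- score[-1L]
  }
  out <- tibble::tibble(from = from, to = to)
  if (any(!is.na(score))) out$score <- score
  if (!is.null(min_score) && "score" %in% names(out)) {
    out <- out[!is.na(out$score) & out$score >= min_score, ]
  }
  out
}

#' Write an edge list to TSV
#'
#' @param edges Tibble with columns `from`, `to` (and optionally `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Build an undirected PPI graph induced on a protein set
#'
#' Keeps edges whose two endpoints both belong to `proteins`, drops
#' self-loops, and merges duplicate/reversed edges. Proteins without any
#' retained edge stay in the graph as isolated nodes.
#'
#' @param proteins Character vector of node ids.
#' @param edges Edge tibble (see [read_edge_list()]) or a path to an edge
#'   list file.
#' @param min_score Optional score threshold forwarded to
#'   [read_edge_list()] when `edges` is a path.
#' @return A `ppi_graph`: a list with the underlying `igraph` object and a
#'   node table (`node`, `degree`); see [degree_zscores()].
#' @export
build_graph <- function(proteins, edges, min_score = NULL) {
  proteins <- unique(as.character(proteins))
  if (is.character(edges) && length(edges) == 1L) {
    edges <- read_edge_list(edges, min_score = min_score)
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  keep <- edges$from %in% proteins & edges$to %in% proteins &
    edges$from != edges$to
  e <- edges[keep, c("from", "to")]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = proteins)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new_ppi_graph(g)
}

new_ppi_graph <- function(g) {
  deg <- igraph::degree(g)
  structure(
    list(
      graph = g,
      nodes = tibble::tibble(node = names(deg), degree = as.integer(deg))
    ),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if ("zd" %in% names(x$nodes)) {
    cat(sprintf("  max degree z-score = %.3g\n", max(x$nodes$zd)))
  }
  invisible(x)
}

#' @export
tidy.ppi_graph <- function(x, ...) x$nodes

#' @export
glance.ppi_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    max_degree = max(x$nodes$degree),
    max_zd = if ("zd" %in% names(x$nodes)) max(x$nodes$zd) else NA_real_
  )
}

#' Degree z-scores of a PPI graph
#'
#' Standardizes each node's degree against the graph's degree distribution:
#' `zd = (deg - mean(deg)) / sd_pop(deg)` with the population (n-denominator)
#' standard deviation. A constant-degree graph gets `zd = 0` everywhere by
#' convention.
#'
#' @param graph A `ppi_graph` (needs at least 2 nodes).
#' @return The `ppi_graph` with a `zd` column added to its node table.
#' @export
degree_zscores <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  deg <- graph$nodes$degree
  if (length(deg) < 2L) stop("need at least 2 nodes for degree z-scores")
  sd_pop <- sqrt(mean((deg - mean(deg))^2))
  graph$nodes$zd <- if (sd_pop == 0) {
    rep(0, length(deg))
  } else {
    (deg - mean(deg)) / sd_pop
  }
  graph
}

#' Select hub nodes by degree z-score
#'
#' @param graph A `ppi_graph` with z-scores (see [degree_zscores()]).
#' @param zd_cut Minimum degree z-score (inclusive); 1 marks connected
#'   nodes, 3 marks strong hubs.
#' @return Node tibble (`node`, `degree`, `zd`) with `zd >= zd_cut`, sorted
#'   by degree descending, ties broken by node id.
#' @export
select_hubs <- function(graph, zd_cut = 3) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!"zd" %in% names(graph$nodes)) graph <- degree_zscores(graph)
  graph$nodes |>
    dplyr::filter(.data$zd >= zd_cut) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}
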