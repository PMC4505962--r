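#' Write a graph as a plain-text edge list
#'
#' Format: a header line `# nodes=<n>` followed by one edge per line,
#' two whitespace-separated 0-based node ids, smaller id first, edges
#' sorted lexicographically. The explicit node count preserves isolated
#' vertices (which cannot occur in grown graphs but can in fixtures).
#'
#' @param graph an `igraph` graph.
#' @param path output file path.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes=%d", igraph::gorder(graph)), con)
  writeLines(sprintf("%d %d", el[, 1L], el[, 2L]), con)
  invisible(path)
}

#' Read a graph written by [write_edgelist()]
#'
#' @param path edge-list file path.
#' @return an `igraph` graph.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# nodes=\\d+$", lines[1L])) {
    stop("missing '# nodes=<n>' header in ", path)
  }
  n <- as.integer(sub("^# nodes=", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(body)) {
    el <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    el <- matrix(as.integer(el), ncol = 2L)
    if (any(el < 0L) || any(el >= n)) stop("edge references node id outside 0..n-1")
    g <- igraph::add_edges(g, t(el + 1L))
  }
  g
}

#' Write a graph to GraphML
#' @param graph an `igraph` graph.
#' @param path output file path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML graph
#' @param path GraphML file path.
#' @return an `igraph` graph.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
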