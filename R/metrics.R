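#' Degree distribution and complementary CDF
#'
#' @param graph a non-empty `igraph` graph.
#' @return data.frame with one row per observed degree (ascending):
#'   `degree`, `count`, and `ccdf` — the fraction of nodes with at
#'   least that degree (non-increasing; 1 at the minimum degree).
#' @export
degree_distribution_table <- function(graph) {
  n <- igraph::gorder(graph)
  if (n == 0L) stop("empty graph")
  deg <- igraph::degree(graph)
  tab <- table(deg)
  d <- as.integer(names(tab))
  count <- as.integer(tab)
  data.frame(degree = d, count = count,
             ccdf = rev(cumsum(rev(count))) / n)
}

#' Log-log slope of the degree CCDF tail
#'
#' Least-squares slope of log10(ccdf) on log10(degree) over a degree
#' window. For a scale-free network with degree density exponent -3
#' (linear preferential attachment), the CCDF slope is close to -2.
#'
#' @param dd a table from [degree_distribution_table()] or a graph.
#' @param degree_range inclusive degree window for the fit.
#' @return the fitted slope.
#' @export
ccdf_slope <- function(dd, degree_range = c(3, 100)) {
  if (inherits(dd, "igraph")) dd <- degree_distribution_table(dd)
  keep <- dd$degree >= degree_range[1L] & dd$degree <= degree_range[2L]
  if (sum(keep) < 3L) stop("fewer than 3 degree values in the fit window")
  x <- log10(dd$degree[keep])
  y <- log10(dd$ccdf[keep])
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs
#' (breadth-first search). Exact when the graph has at most
#' `max_exact_n` nodes; otherwise estimated from `n_sources` uniformly
#' sampled source nodes and flagged as sampled.
#'
#' @param graph a connected `igraph` graph.
#' @param max_exact_n largest size for the exact all-pairs computation.
#' @param n_sources number of sampled sources in the large-graph mode.
#' @param seed optional seed for the source sample.
#' @return list with `value` and logical `exact`.
#' @export
characteristic_path_length <- function(graph, max_exact_n = 2000L,
                                       n_sources = 1000L, seed = NULL) {
  if (!igraph::is_connected(graph)) {
    stop("characteristic path length is undefined for disconnected graphs")
  }
  n <- igraph::gorder(graph)
  if (n <= max_exact_n) {
    return(list(value = igraph::mean_distance(graph), exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  src <- sample.int(n, min(n_sources, n))
  D <- igraph::distances(graph, v = src)
  # mean over source-to-other distances, excluding self-distances
  list(value = sum(D) / (length(src) * (n - 1L)), exact = FALSE)
}

#' Mean local clustering coefficient
#'
#' Per node: the fraction of pairs of its neighbors that are themselves
#' connected; 0 by convention for nodes of degree < 2. Returns the
#' unweighted mean over all nodes.
#'
#' @param graph a non-empty `igraph` graph.
#' @return scalar in `[0, 1]`.
#' @export
mean_local_clustering <- function(graph) {
  if (igraph::gorder(graph) == 0L) stop("empty graph")
  mean(igraph::transitivity(graph, type = "localundirected",
                            isolates = "zero"))
}

#' All connectivity metrics of a graph
#'
#' @inheritParams characteristic_path_length
#' @param degree_range CCDF slope fit window; slope is NA when the
#'   window holds fewer than 3 distinct degrees.
#' @return a `network_metrics` object: `degree_table`,
#'   `char_path_length`, `path_length_exact`, `mean_clustering`,
#'   `ccdf_slope`, `n_nodes`, `n_edges`.
#' @export
network_metrics <- function(graph, max_exact_n = 2000L, n_sources = 1000L,
                            seed = NULL, degree_range = c(3, 100)) {
  dd <- degree_distribution_table(graph)
  cpl <- characteristic_path_length(graph, max_exact_n, n_sources, seed)
  slope <- tryCatch(ccdf_slope(dd, degree_range), error = function(e) NA_real_)
  structure(list(degree_table = dd,
                 char_path_length = cpl$value,
                 path_length_exact = cpl$exact,
                 mean_clustering = mean_local_clustering(graph),
                 ccdf_slope = slope,
                 n_nodes = igraph::gorder(graph),
                 n_edges = igraph::gsize(graph)),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<network_metrics> %d nodes, %d edges; path length %.3f",
           " (%s), clustering %.4f, CCDF slope %s\n"),
    x$n_nodes, x$n_edges, x$char_path_length,
    if (x$path_length_exact) "exact" else "sampled",
    x$mean_clustering,
    if (is.na(x$ccdf_slope)) "NA" else sprintf("%.2f", x$ccdf_slope)))
  invisible(x)
}

metrics_to_json <- function(x, path) {
  jsonlite::write_json(
    list(n_nodes = x$n_nodes, n_edges = x$n_edges,
         char_path_length = x$char_path_length,
         path_length_exact = x$path_length_exact,
         mean_clustering = x$mean_clustering,
         ccdf_slope = x$ccdf_slope,
         degree_counts = stats::setNames(as.list(x$degree_table$count),
                                         x$degree_table$degree)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
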