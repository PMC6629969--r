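# Summary measures and per-node structural features used to compare
# networks and to feed the utility function.

#' Compute the summary metrics of a network
#'
#' Computes the measure set used throughout the package to compare a model
#' network against a reference connectome: average (local) clustering
#' coefficient, average shortest path length over reachable ordered pairs,
#' average neighbour count, diameter (largest finite distance), average
#' normalized betweenness, degree homogeneity and density, plus the degree,
#' shortest-path and betweenness distributions.
#'
#' Conventions: clustering is always computed on the undirected projection
#' (nodes with fewer than two neighbours contribute 0); `avg_neighbors` is
#' `2 * |undirected edges| / n`; homogeneity is `mean(k)^2 / mean(k^2)` over
#' undirected degrees (1 for regular graphs, small for heavy-tailed ones);
#' path metrics and density respect the `directed` flag. Graphs with no
#' reachable pair report `NA` path metrics rather than erroring.
#'
#' @param graph a neural graph (directed igraph; an undirected igraph is
#'   accepted and treated as its own projection).
#' @param directed logical; if `FALSE` all measures are taken on the
#'   undirected projection.
#' @return an object of class `metrics_report`: a list with scalar fields
#'   `avg_clustering`, `avg_shortest_path`, `avg_neighbors`, `diameter`,
#'   `avg_betweenness`, `homogeneity`, `density` and distribution fields
#'   `in_degree_hist`, `out_degree_hist`, `shortest_path_hist`,
#'   `betweenness_values`.
#' @examples
#' g <- neural_graph(cbind(letters[1:3], letters[2:4]), directed = FALSE)
#' compute_metrics(g)$avg_shortest_path  # P4: 10/6
#' @export
compute_metrics <- function(graph, directed = FALSE) {
  validate_neural_graph(graph)
  if (igraph::vcount(graph) == 0L) stop("graph is empty")
  und <- if (igraph::is_directed(graph)) {
    igraph::as_undirected(graph, mode = "collapse")
  } else {
    graph
  }
  gw <- if (directed && igraph::is_directed(graph)) graph else und
  dir_flag <- directed && igraph::is_directed(graph)
  n <- igraph::vcount(graph)

  lc <- igraph::transitivity(und, type = "local", isolates = "zero")
  dmat <- igraph::distances(gw, mode = if (dir_flag) "out" else "all")
  finite <- dmat[is.finite(dmat) & dmat > 0]
  k <- igraph::degree(und, mode = "all")
  bw <- igraph::betweenness(gw, directed = dir_flag, normalized = n > 2L)

  structure(list(
    avg_clustering = mean(lc),
    avg_shortest_path = if (length(finite) > 0L) mean(finite) else NA_real_,
    avg_neighbors = 2 * igraph::ecount(und) / n,
    diameter = if (length(finite) > 0L) as.integer(max(finite)) else NA_integer_,
    avg_betweenness = mean(bw),
    homogeneity = if (any(k > 0)) mean(k)^2 / mean(k^2) else NA_real_,
    density = igraph::edge_density(gw),
    in_degree_hist = degree_hist(gw, mode = if (dir_flag) "in" else "all"),
    out_degree_hist = degree_hist(gw, mode = if (dir_flag) "out" else "all"),
    shortest_path_hist = path_hist(finite),
    betweenness_values = bw,
    directed = dir_flag
  ), class = "metrics_report")
}

#' @noRd
degree_hist <- function(g, mode) {
  d <- igraph::degree(g, mode = mode)
  tb <- table(factor(d, levels = 0:max(c(d, 0))))
  data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
}

#' @noRd
path_hist <- function(finite) {
  if (length(finite) == 0L) {
    return(data.frame(length = integer(), count = integer()))
  }
  tb <- table(finite)
  data.frame(length = as.integer(names(tb)), count = as.integer(tb))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Network metrics (", if (x$directed) "directed" else "undirected", "):\n", sep = "")
  for (f in c("avg_clustering", "avg_shortest_path", "avg_neighbors",
              "diameter", "avg_betweenness", "homogeneity", "density")) {
    cat(sprintf("  %-18s %s\n", f, format(x[[f]], digits = 6)))
  }
  invisible(x)
}

#' Structural features of one node
#'
#' The four per-node features entering the utility function: `S`, the mean
#' shortest-path length from the node to its reachable peers; `P`, PageRank
#' (damping 0.85) on the directed graph; `C`, closeness, the reciprocal of
#' the mean distance to reachable peers; `Be`, normalized betweenness. `S`,
#' `C` and `Be` are taken on the undirected projection, matching the
#' pairwise framing of the game. An isolated node has `S = NA`, `C = 0`,
#' `Be = 0`.
#'
#' @param graph a neural graph.
#' @param node a node id (character) present in the graph.
#' @return named numeric vector `c(S, P, C, Be)`.
#' @export
node_features <- function(graph, node) {
  validate_neural_graph(graph)
  if (!node %in% igraph::V(graph)$name) stop("no such node: ", node)
  A <- adj_from_graph(graph)
  i <- match(node, rownames(A))
  f <- state_features(A, i)
  if (f[1, "C"] == 0) f[1, "S"] <- NA_real_  # isolated: sentinel to NA
  c(S = unname(f[1, "S"]), P = unname(f[1, "P"]),
    C = unname(f[1, "C"]), Be = unname(f[1, "Be"]))
}

#' Compare metric reports across networks
#'
#' Tabulates the scalar measures of two or more [compute_metrics()] reports
#' side by side, with the absolute difference of each network against the
#' first (reference) report.
#'
#' @param reports list of `metrics_report` objects.
#' @param labels character vector of network labels, one per report.
#' @return a data frame with one row per measure, one value column per
#'   network and one `diff_<label>` column per non-reference network.
#' @export
compare_networks <- function(reports, labels = NULL) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  if (is.null(labels)) labels <- paste0("network_", seq_along(reports))
  if (length(labels) != length(reports)) stop("one label per report required")
  measures <- c("avg_clustering", "avg_shortest_path", "avg_neighbors",
                "diameter", "avg_betweenness", "homogeneity", "density")
  vals <- vapply(reports, function(r) {
    vapply(measures, function(m) as.numeric(r[[m]]), numeric(1))
  }, numeric(length(measures)))
  colnames(vals) <- labels
  out <- data.frame(measure = measures, vals, check.names = FALSE)
  for (j in seq_along(labels)[-1]) {
    out[[paste0("diff_", labels[j])]] <- abs(vals[, j] - vals[, 1])
  }
  rownames(out) <- NULL
  out
}
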