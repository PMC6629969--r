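# Reading and writing attributed directed graphs and reports.

ATTR_COLUMNS <- c("neuron_id", "x_um", "y_um", "z_um", "birth_time_min")

#' Construct a neural graph
#'
#' A neural graph is a simple directed [igraph][igraph::igraph-package]
#' graph with unique character vertex names, no self-loops and no duplicate
#' edges. All modelling functions in the package expect this form.
#'
#' @param edges two-column character matrix or data frame of directed edges
#'   (source, target); may be empty.
#' @param nodes optional character vector of node ids; the node set is the
#'   union of `nodes` and all edge endpoints.
#' @param directed logical; if `FALSE` an undirected graph is built (used
#'   for the undirected random-network baselines).
#' @return an igraph graph with vertex names.
#' @examples
#' g <- neural_graph(rbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(g)
#' @export
neural_graph <- function(edges, nodes = NULL, directed = TRUE) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), 0, 2)
  if (ncol(edges) != 2L) stop("`edges` must have two columns (source, target)")
  storage.mode(edges) <- "character"
  ids <- sort(unique(c(nodes, as.vector(edges))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  validate_neural_graph(g)
  g
}

#' Validate the neural-graph invariants
#'
#' Checks that a graph is simple (no self-loops, no duplicate edges) and has
#' unique character vertex names. Called by every reader and generator.
#'
#' @param g an igraph graph.
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_neural_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph graph")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyDuplicated(nm) || any(is.na(nm)) || any(nm == "")) {
    stop("graph vertices must carry unique non-empty names")
  }
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops/multi-edges)")
  invisible(g)
}

#' Read a directed edge list
#'
#' Reads a plain-text edge list, one `source target` pair per line,
#' whitespace-separated, with `#` comments. Duplicate edges are collapsed
#' and self-loops dropped, each with a warning (connectome exports commonly
#' contain both); the node set is the union of all endpoints.
#'
#' @param path file path.
#' @param directed logical; if `FALSE` the edge list is symmetrized on read
#'   and an undirected graph returned.
#' @return a neural graph (see [neural_graph()]).
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  toks <- strsplit(trimws(stripped[keep]), "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    bad <- keep[which(nt != 2L)[1]]
    stop("malformed edge-list line ", bad, " in ", path,
         " (expected 2 tokens, got ", nt[which(nt != 2L)[1]], ")")
  }
  em <- do.call(rbind, toks)
  if (length(em) == 0L) em <- matrix(character(), 0, 2)
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped while reading ", path)
  }
  key <- if (directed) {
    paste(em[, 1], em[, 2])
  } else {
    paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  }
  dup <- duplicated(key) & !loops
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed while reading ", path)
  }
  em2 <- em[!loops & !dup, , drop = FALSE]
  neural_graph(em2, nodes = unique(as.vector(em)), directed = directed)
}

#' Read a neuron attribute table
#'
#' Reads a CSV with header `neuron_id,x_um,y_um,z_um,birth_time_min`:
#' 3-D soma position in micrometres and birth time in minutes. When a graph
#' is supplied, every graph node must have a row (missing nodes are an
#' error); rows for neurons absent from the graph are kept with a warning.
#'
#' @param path CSV file path.
#' @param graph optional neural graph to check coverage against.
#' @return a data frame with the five attribute columns.
#' @export
read_attributes <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ATTR_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("attribute table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, ATTR_COLUMNS]
  df$neuron_id <- as.character(df$neuron_id)
  num <- c("x_um", "y_um", "z_um", "birth_time_min")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-numeric or non-finite value in column ", cl, " of ", path)
    }
    df[[cl]] <- v
  }
  if (anyDuplicated(df$neuron_id)) {
    stop("duplicate neuron_id in ", path)
  }
  if (any(df$birth_time_min < 0)) stop("negative birth_time_min in ", path)
  if (!is.null(graph)) {
    ids <- igraph::V(graph)$name
    absent <- setdiff(ids, df$neuron_id)
    if (length(absent) > 0L) {
      stop("attribute table missing graph node(s): ",
           paste(absent, collapse = ", "))
    }
    extra <- setdiff(df$neuron_id, ids)
    if (length(extra) > 0L) {
      warning(length(extra), " attribute row(s) for neurons not in the graph")
    }
  }
  df
}

#' Write a graph and report to disk
#'
#' Serializes a neural graph to GraphML and to a plain edge list, and an
#' arbitrary report (named list) to JSON. Reading the written edge list or
#' GraphML back reproduces the node and edge sets exactly.
#'
#' @param graph a neural graph.
#' @param report named list of results, or `NULL` to skip.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(graph, report = NULL, out_dir = ".", prefix = "network") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    graphml = file.path(out_dir, paste0(prefix, ".graphml")),
    edgelist = file.path(out_dir, paste0(prefix, ".edgelist"))
  )
  igraph::write_graph(graph, paths[["graphml"]], format = "graphml")
  write_edge_list(graph, paths[["edgelist"]])
  if (!is.null(report)) {
    paths <- c(paths, report = file.path(out_dir, paste0(prefix, "_report.json")))
    jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(paths)
}

#' Write a plain-text edge list
#'
#' One `source target` line per edge; isolated nodes are recorded as
#' `# node <id>` comment lines so the node set round-trips.
#'
#' @param graph a neural graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  deg <- igraph::degree(graph, mode = "all")
  iso <- names(deg)[deg == 0]
  lines <- c(
    paste(el[, 1], el[, 2]),
    if (length(iso) > 0L) paste("# node", iso)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' Same format as [read_edge_list()], but `# node <id>` comments are parsed
#' back into isolated nodes so the round trip is exact.
#'
#' @inheritParams read_edge_list
#' @return a neural graph.
#' @export
read_edge_list_full <- function(path, directed = TRUE) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^#[[:space:]]*node[[:space:]]+", "",
             grep("^#[[:space:]]*node[[:space:]]+", lines, value = TRUE))
  g <- read_edge_list(path, directed = directed)
  if (length(iso) > 0L) {
    g <- igraph::add_vertices(g, length(setdiff(iso, igraph::V(g)$name)),
                              name = setdiff(iso, igraph::V(g)$name))
  }
  validate_neural_graph(g)
  g
}

#' Write an attribute table
#'
#' @param attrs attribute data frame (see [read_attributes()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(attrs, path) {
  write.csv(attrs[, ATTR_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
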