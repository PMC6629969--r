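# Internal feature machinery shared by the game, stability and fitting code.
#
# All hot-loop work happens on a named logical adjacency matrix A (directed,
# rows = sources) whose row/column order is the lexicographic order of the
# node ids; this makes pair enumeration and tie-breaking reproducible across
# graphs regardless of igraph vertex order.  Single-source distances are a
# plain BFS on the undirected projection; PageRank and betweenness delegate
# to igraph.

FEATURE_NAMES <- c("D", "B", "S", "P", "C", "Be")
COEF_NAMES <- c("alpha", "beta", "lambda", "rho", "theta", "omega")

#' @noRd
adj_from_graph <- function(g) {
  ids <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  if (!igraph::is_directed(g)) A <- A | t(A)
  A <- A[igraph::V(g)$name, igraph::V(g)$name, drop = FALSE]
  A[ids, ids, drop = FALSE]
}

#' @noRd
graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A * 1L, mode = "directed")
}

# Single-source BFS distances on an undirected logical adjacency matrix.
# Returns numeric vector with Inf for unreachable nodes.
#' @noRd
bfs_dists <- function(U, src) {
  n <- nrow(U)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  lev <- 0
  while (length(frontier) > 0L) {
    lev <- lev + 1
    if (length(frontier) == 1L) {
      nbr <- which(U[frontier, ])
    } else {
      nbr <- which(colSums(U[frontier, , drop = FALSE]) > 0L)
    }
    frontier <- nbr[is.infinite(d[nbr])]
    d[frontier] <- lev
  }
  d
}

# S (mean shortest path to reachable peers) and C (reciprocal of that mean)
# for selected nodes.  A node with no reachable peer gets the penalty
# sentinel S = n and C = 0 so the game dynamics remain well defined.
#' @noRd
sc_features <- function(U, nodes, sentinel = nrow(U)) {
  out <- matrix(0, length(nodes), 2, dimnames = list(NULL, c("S", "C")))
  for (k in seq_along(nodes)) {
    d <- bfs_dists(U, nodes[k])[-nodes[k]]
    d <- d[is.finite(d)]
    if (length(d) == 0L) {
      out[k, ] <- c(sentinel, 0)
    } else {
      m <- mean(d)
      out[k, ] <- c(m, 1 / m)
    }
  }
  out
}

# Full per-state structural features for endpoints `nodes` of a directed
# adjacency matrix.  `need` is a logical vector over c(S, P, C, Be); features
# not needed are returned as 0 (their utility weight is 0 in that case).
#' @noRd
state_features <- function(A, nodes, need = c(S = TRUE, P = TRUE, C = TRUE, Be = TRUE)) {
  U <- A | t(A)
  f <- matrix(0, length(nodes), 4, dimnames = list(NULL, c("S", "P", "C", "Be")))
  if (need[["S"]] || need[["C"]]) {
    sc <- sc_features(U, nodes)
    if (need[["S"]]) f[, "S"] <- sc[, "S"]
    if (need[["C"]]) f[, "C"] <- sc[, "C"]
  }
  if (need[["P"]]) {
    pr <- igraph::page_rank(graph_from_adj(A), damping = 0.85)$vector
    f[, "P"] <- pr[nodes]
  }
  if (need[["Be"]]) {
    gu <- igraph::graph_from_adjacency_matrix(U * 1L, mode = "undirected")
    be <- igraph::betweenness(gu, directed = FALSE, normalized = nrow(U) > 2L)
    f[, "Be"] <- be[nodes]
  }
  f
}

# Toggle helpers ------------------------------------------------------------

#' @noRd
drop_pair_edges <- function(A, i, j) {
  A[i, j] <- FALSE
  A[j, i] <- FALSE
  A
}

# `dir` is one of "low_to_high" (edge from the lexicographically smaller id,
# i.e. the smaller matrix index, since the matrix is id-sorted), "i_to_j",
# "j_to_i", "both".
#' @noRd
add_pair_edge <- function(A, i, j, dir = "low_to_high") {
  if (dir == "both") {
    A[i, j] <- TRUE
    A[j, i] <- TRUE
  } else if (dir == "i_to_j" || (dir == "low_to_high" && i < j)) {
    A[i, j] <- TRUE
  } else {
    A[j, i] <- TRUE
  }
  A
}

# Feature matrices (rows = endpoints i, j; cols = the six features) for the
# linked and unlinked state of one unordered pair.  In the linked state the
# D and B columns carry the pair's distance and birth-time difference; in
# the unlinked state they are 0 (the link-cost terms vanish without a link).
#' @noRd
pair_state_features <- function(A, i, j, Dm, Bm,
                                need = c(S = TRUE, P = TRUE, C = TRUE, Be = TRUE),
                                add_dir = "low_to_high") {
  linked <- A[i, j] || A[j, i]
  A_lnk <- if (linked) A else add_pair_edge(A, i, j, add_dir)
  A_unl <- if (linked) drop_pair_edges(A, i, j) else A
  s_lnk <- state_features(A_lnk, c(i, j), need)
  s_unl <- state_features(A_unl, c(i, j), need)
  f_lnk <- cbind(D = rep(Dm[i, j], 2), B = rep(Bm[i, j], 2), s_lnk)
  f_unl <- cbind(D = c(0, 0), B = c(0, 0), s_unl)
  list(linked = linked, f_lnk = f_lnk, f_unl = f_unl,
       delta = f_lnk - f_unl)
}

# Pairwise attribute matrices (soma distance, birth-time difference) in the
# id-sorted node order of `ids`.
#' @noRd
attr_matrices <- function(attrs, ids) {
  rows <- match(ids, attrs$neuron_id)
  if (anyNA(rows)) {
    stop("attributes missing for node(s): ",
         paste(ids[is.na(rows)], collapse = ", "))
  }
  pos <- as.matrix(attrs[rows, c("x_um", "y_um", "z_um")])
  rownames(pos) <- ids
  birth <- setNames(attrs$birth_time_min[rows], ids)
  Dm <- as.matrix(dist(pos))
  Bm <- abs(outer(birth, birth, "-"))
  dimnames(Dm) <- dimnames(Bm) <- list(ids, ids)
  list(D = Dm, B = Bm)
}

#' @noRd
needed_features <- function(coeffs, all = FALSE) {
  if (all) return(c(S = TRUE, P = TRUE, C = TRUE, Be = TRUE))
  c(S = coeffs[["lambda"]] != 0, P = coeffs[["rho"]] != 0,
    C = coeffs[["theta"]] != 0, Be = coeffs[["omega"]] != 0)
}

#' @noRd
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
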