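# Shared fixtures and the independent brute-force stability oracle.
# The oracle computes node utilities straight from igraph metrics and
# enumerates every single-link deviation; it shares no code with the
# package's stability/evolution path.

rand_attrs <- function(n, seed = 1L, ids = sprintf("v%03d", seq_len(n))) {
  withr::with_seed(seed, data.frame(
    neuron_id = ids,
    x_um = runif(n), y_um = runif(n), z_um = runif(n),
    birth_time_min = runif(n)))
}

rand_digraph <- function(n, p, seed = 1L, ids = sprintf("v%03d", seq_len(n))) {
  withr::with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- runif(nrow(pairs)) < p
    neural_graph(cbind(ids[pairs$from[keep]], ids[pairs$to[keep]]),
                 nodes = ids, directed = TRUE)
  })
}

rand_coeffs <- function(seed = 1L) {
  withr::with_seed(seed, {
    x <- runif(6, -1, 1)
    x[runif(6) < 0.3] <- 0  # some zero weights, as in fitted signatures
    utility_coefficients(x[1], x[2], x[3], x[4], x[5], x[6])
  })
}

# Utility of node `i` against partner `j` in graph state `g`, computed
# independently via igraph.
oracle_node_utility <- function(g, attrs, i, j, co) {
  co <- unclass(co)
  n <- igraph::vcount(g)
  und <- igraph::as_undirected(g, mode = "collapse")
  d <- igraph::distances(und, v = i)[1, ]
  d <- d[setdiff(names(d), i)]
  d <- d[is.finite(d)]
  S <- if (length(d) == 0L) n else mean(d)
  C <- if (length(d) == 0L) 0 else 1 / mean(d)
  P <- igraph::page_rank(g, damping = 0.85)$vector[[i]]
  Be <- igraph::betweenness(und, v = i, directed = FALSE,
                            normalized = n > 2)[[1]]
  linked <- igraph::are_adjacent(g, i, j) || igraph::are_adjacent(g, j, i)
  r <- match(c(i, j), attrs$neuron_id)
  D <- sqrt(sum((as.numeric(attrs[r[1], c("x_um", "y_um", "z_um")]) -
                 as.numeric(attrs[r[2], c("x_um", "y_um", "z_um")]))^2))
  B <- abs(attrs$birth_time_min[r[1]] - attrs$birth_time_min[r[2]])
  (if (linked) co[["alpha"]] * D + co[["beta"]] * B else 0) +
    co[["lambda"]] * S + co[["rho"]] * P + co[["theta"]] * C +
    co[["omega"]] * Be
}

oracle_toggle <- function(g, i, j) {
  linked <- igraph::are_adjacent(g, i, j) || igraph::are_adjacent(g, j, i)
  if (linked) {
    eids <- igraph::get_edge_ids(g, rbind(c(i, j), c(j, i)), error = FALSE)
    igraph::delete_edges(g, eids[eids > 0])
  } else {
    # hypothetical added link: lexicographically smaller id is the source
    igraph::add_edges(g, if (i < j) c(i, j) else c(j, i))
  }
}

# Brute-force pairwise-stability verdict by enumerating all single-link
# deviations.
oracle_pairwise_stable <- function(g, attrs, co, tol = 1e-12) {
  ids <- sort(igraph::V(g)$name)
  n <- length(ids)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      i <- ids[a]; j <- ids[b]
      linked <- igraph::are_adjacent(g, i, j) || igraph::are_adjacent(g, j, i)
      g2 <- oracle_toggle(g, i, j)
      ui <- oracle_node_utility(g, attrs, i, j, co)
      uj <- oracle_node_utility(g, attrs, j, i, co)
      ui2 <- oracle_node_utility(g2, attrs, i, j, co)
      uj2 <- oracle_node_utility(g2, attrs, j, i, co)
      if (linked) {
        # deletion is unilateral: unstable if either endpoint strictly gains
        if (ui2 - ui > tol || uj2 - uj > tol) return(FALSE)
      } else {
        # blocked add: unstable if one strictly gains and the other weakly
        if ((ui2 - ui > tol && uj2 - uj >= -tol) ||
            (uj2 - uj > tol && ui2 - ui >= -tol)) return(FALSE)
      }
    }
  }
  TRUE
}

TRUE_COEFFS <- utility_coefficients(alpha = -1, beta = -0.5, lambda = -0.1,
                                    rho = 0, theta = -0.25, omega = 0)
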