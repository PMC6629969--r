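# The six reference-matched random-network generators used as candidate
# base networks and comparison baselines.  All generators are
# seed-deterministic: the same parameters and seed give an identical edge
# set.

#' @noRd
default_ids <- function(n) sprintf("v%03d", seq_len(n))

#' Directed Havel-Hakimi realization of an in/out degree sequence
#'
#' Constructively realizes a prescribed pair of in- and out-degree
#' sequences as a simple digraph (no self-loops, no duplicate edges), or
#' errors if the pair is not di-graphical. The greedy Kleitman-Wang scheme
#' is used: the node with the largest remaining out-degree wires all its
#' out-stubs to the nodes with the largest remaining in-degrees; ties are
#' broken uniformly at random under `seed`, so the family of realizations
#' is sampled rather than a single canonical graph.
#'
#' @param in_seq,out_seq non-negative integer vectors of equal length with
#'   equal sums; `in_seq[k]` and `out_seq[k]` are the target in- and
#'   out-degree of node `k`.
#' @param seed integer seed for tie-breaking.
#' @param ids optional node ids (default `v001`, `v002`, ...).
#' @return a neural graph whose degree sequences equal the inputs exactly.
#' @examples
#' g <- havel_hakimi_directed(c(1, 1, 0), c(0, 1, 1), seed = 1)
#' igraph::degree(g, mode = "in")
#' @export
havel_hakimi_directed <- function(in_seq, out_seq, seed = 1L, ids = NULL) {
  n <- length(in_seq)
  if (length(out_seq) != n) stop("in_seq and out_seq must have equal length")
  if (any(in_seq < 0) || any(out_seq < 0) ||
      any(in_seq != round(in_seq)) || any(out_seq != round(out_seq))) {
    stop("degree sequences must be non-negative integers")
  }
  if (sum(in_seq) != sum(out_seq)) {
    stop("not di-graphical: in/out degree sums differ (",
         sum(in_seq), " vs ", sum(out_seq), ")")
  }
  if (any(in_seq > n - 1) || any(out_seq > n - 1)) {
    stop("not di-graphical: degree exceeds n - 1")
  }
  if (is.null(ids)) ids <- default_ids(n)
  rin <- as.integer(in_seq)
  rout <- as.integer(out_seq)
  from <- integer(0)
  to <- integer(0)
  withr::with_seed(as.integer(seed), {
    while (any(rout > 0L)) {
      cand <- which(rout == max(rout))
      v <- if (length(cand) == 1L) cand else sample(cand, 1L)
      k <- rout[v]
      pool <- setdiff(which(rin > 0L), v)
      if (length(pool) < k) {
        stop("not di-graphical: cannot place ", k,
             " out-edge(s) of node ", ids[v])
      }
      # Kleitman-Wang: targets in decreasing lexicographic order of
      # (remaining in-degree, remaining out-degree); random among exact ties
      ord <- order(-rin[pool], -rout[pool], runif(length(pool)))
      tgt <- pool[ord[seq_len(k)]]
      from <- c(from, rep(v, k))
      to <- c(to, tgt)
      rout[v] <- 0L
      rin[tgt] <- rin[tgt] - 1L
    }
  })
  g <- neural_graph(cbind(ids[from], ids[to]), nodes = ids, directed = TRUE)
  stopifnot(all(igraph::degree(g, ids, mode = "in") == in_seq),
            all(igraph::degree(g, ids, mode = "out") == out_seq))
  g
}

#' Directed Erdos-Renyi random graph
#'
#' Each of the `n (n - 1)` ordered node pairs carries an edge independently
#' with probability `p`.
#'
#' @param n node count.
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @param ids optional node ids.
#' @return a directed neural graph.
#' @export
erdos_renyi_directed <- function(n, p, seed = 1L, ids = NULL) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (is.null(ids)) ids <- default_ids(n)
  g <- withr::with_seed(as.integer(seed),
                        igraph::sample_gnp(n, p, directed = TRUE))
  igraph::V(g)$name <- ids
  validate_neural_graph(g)
  g
}

#' Distance-based Watts-Strogatz network
#'
#' A small-world generator whose regular stage is driven by physical
#' distance rather than a ring: each node is first linked to its `k`
#' nearest neighbours by Euclidean soma distance (undirected union, so
#' every node ends with degree at least `k`); each edge is then rewired
#' with probability `rewire_p`, replacing `(u, v)` by `(u, w)` for a
#' uniformly chosen new partner `w` (rewiring moves edges, never deletes
#' them). Distance ties are broken lexicographically by node id.
#'
#' @param attrs attribute table supplying node ids and soma positions.
#' @param k number of nearest neighbours wired in the regular stage.
#' @param rewire_p per-edge rewiring probability.
#' @param seed integer seed.
#' @return an undirected neural graph.
#' @export
watts_strogatz_distance <- function(attrs, k = 5L, rewire_p = 0.5, seed = 1L) {
  ids <- sort(as.character(attrs$neuron_id))
  n <- length(ids)
  if (k >= n) stop("k must be smaller than the node count")
  pos <- as.matrix(attrs[match(ids, attrs$neuron_id), c("x_um", "y_um", "z_um")])
  Dm <- as.matrix(dist(pos))
  # stage 1: k nearest neighbours per node, ties lexicographic by id
  pairs <- matrix(integer(), 0, 2)
  for (i in seq_len(n)) {
    ord <- order(Dm[i, -i], seq_len(n)[-i])
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  withr::with_seed(as.integer(seed), {
    adj <- matrix(FALSE, n, n)
    adj[pairs] <- TRUE
    adj[pairs[, 2:1, drop = FALSE]] <- TRUE
    for (e in seq_len(nrow(pairs))) {
      if (runif(1) < rewire_p) {
        u <- pairs[e, 1]; v <- pairs[e, 2]
        if (!adj[u, v]) next  # already moved by an earlier rewire
        cand <- which(!adj[u, ] & seq_len(n) != u)
        if (length(cand) == 0L) next
        w <- if (length(cand) == 1L) cand else sample(cand, 1L)
        adj[u, v] <- adj[v, u] <- FALSE
        adj[u, w] <- adj[w, u] <- TRUE
      }
    }
  })
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  neural_graph(cbind(ids[idx[, 1]], ids[idx[, 2]]), nodes = ids, directed = FALSE)
}

#' Expected-degree (Chung-Lu) random graph
#'
#' Each unordered node pair `(u, v)` carries an edge independently with
#' probability `w_u * w_v / sum(w)`, where `w` is the target expected
#' degree sequence; self-pairs are excluded. Probabilities exceeding 1 are
#' clipped with a warning.
#'
#' @param degree_seq non-negative expected degrees, one per node.
#' @param seed integer seed.
#' @param ids optional node ids.
#' @return an undirected neural graph.
#' @export
expected_degree_graph <- function(degree_seq, seed = 1L, ids = NULL) {
  if (any(degree_seq < 0)) stop("expected degrees must be non-negative")
  n <- length(degree_seq)
  if (is.null(ids)) ids <- default_ids(n)
  if (n < 2L || sum(degree_seq) == 0) {
    return(neural_graph(matrix(character(), 0, 2), nodes = ids, directed = FALSE))
  }
  w <- as.numeric(degree_seq)
  P <- outer(w, w) / sum(w)
  if (any(P[upper.tri(P)] > 1)) {
    warning("edge probabilities > 1 clipped to 1")
    P[P > 1] <- 1
  }
  withr::with_seed(as.integer(seed), {
    U <- matrix(runif(n * n), n, n)
  })
  sel <- which(upper.tri(P) & U < P, arr.ind = TRUE)
  neural_graph(cbind(ids[sel[, 1]], ids[sel[, 2]]), nodes = ids, directed = FALSE)
}

#' Power-law clustering (Holme-Kim) random graph
#'
#' Growing network with preferential attachment plus triad closure: each
#' new node attaches `m` edges; each attachment after the first follows,
#' with probability `triangle_p`, a triangle-closing step that links to a
#' random neighbour of the previously chosen target instead of a fresh
#' preferential draw. With `triangle_p = 0` this reduces to a
#' Barabasi-Albert-type graph with `(n - m) * m` edges.
#'
#' @param n final node count.
#' @param m edges attached by each new node (`1 <= m < n`).
#' @param triangle_p triangle-closure probability.
#' @param seed integer seed.
#' @param ids optional node ids.
#' @return an undirected neural graph.
#' @export
powerlaw_cluster_graph <- function(n, m, triangle_p = 0.2, seed = 1L, ids = NULL) {
  if (m < 1 || m >= n) stop("need 1 <= m < n")
  if (triangle_p < 0 || triangle_p > 1) stop("triangle_p must be in [0, 1]")
  if (is.null(ids)) ids <- default_ids(n)
  m <- as.integer(m)
  nbrs <- vector("list", n)
  repeated <- seq_len(m)  # seed nodes, one nominal stub each
  edges <- matrix(integer(), 0, 2)
  withr::with_seed(as.integer(seed), {
    for (src in (m + 1):n) {
      targets <- integer(0)
      prev <- NA_integer_
      while (length(targets) < m) {
        cand <- NA_integer_
        if (length(targets) > 0L && runif(1) < triangle_p) {
          pool <- setdiff(nbrs[[prev]], c(src, targets))
          if (length(pool) > 0L) {
            cand <- if (length(pool) == 1L) pool else sample(pool, 1L)
          }
        }
        if (is.na(cand)) {
          cand <- repeated[sample.int(length(repeated), 1L)]
          if (cand == src || cand %in% targets) next
        }
        targets <- c(targets, cand)
        prev <- cand
      }
      edges <- rbind(edges, cbind(src, targets))
      for (t in targets) {
        nbrs[[src]] <- c(nbrs[[src]], t)
        nbrs[[t]] <- c(nbrs[[t]], src)
      }
      repeated <- c(repeated, targets, rep(src, m))
    }
  })
  neural_graph(cbind(ids[edges[, 1]], ids[edges[, 2]]), nodes = ids,
               directed = FALSE)
}

#' Directed scale-free random graph
#'
#' Preferential-attachment growth for digraphs: at each event, with
#' probability `alpha` a new node is added with an edge to an existing node
#' chosen proportionally to in-degree plus `delta_in`; with probability
#' `beta` an edge is added between existing nodes (source by out-degree
#' plus `delta_out`, target by in-degree plus `delta_in`); with probability
#' `gamma` a new node is added receiving an edge from an existing node
#' chosen by out-degree. Growth starts from a directed 3-cycle and stops
#' when the node target or the optional edge budget is reached, whichever
#' comes first; because `beta` events add no node, the final node count is
#' not guaranteed to equal `n_target` when an edge budget is given.
#' Candidate `beta` edges that would duplicate an existing edge or form a
#' self-loop are redrawn a bounded number of times, keeping the graph
#' simple.
#'
#' @param n_target node-count target.
#' @param alpha,beta,gamma event probabilities; must sum to 1.
#' @param delta_in,delta_out attachment offsets.
#' @param seed integer seed.
#' @param edges_target optional edge budget; growth stops once reached.
#' @return a directed neural graph.
#' @export
scale_free_directed <- function(n_target, alpha = 0.15, beta = 0.8,
                                gamma = 0.05, delta_in = 0.2, delta_out = 0,
                                seed = 1L, edges_target = NULL) {
  if (abs(alpha + beta + gamma - 1) > 1e-9 || any(c(alpha, beta, gamma) < 0)) {
    stop("alpha + beta + gamma must equal 1 with each term >= 0")
  }
  nv <- 3L
  indeg <- rep(1, nv)
  outdeg <- rep(1, nv)
  from <- c(1L, 2L, 3L)
  to <- c(2L, 3L, 1L)
  has_edge <- new.env(hash = TRUE)
  for (e in seq_along(from)) assign(paste(from[e], to[e]), TRUE, envir = has_edge)
  pick <- function(wt) sample.int(length(wt), 1L, prob = wt)
  iter <- 0L
  max_iter <- 1000L + 100L * (n_target + if (is.null(edges_target)) 0 else edges_target)
  withr::with_seed(as.integer(seed), {
    repeat {
      if (!is.null(edges_target) && length(from) >= edges_target) break
      if (nv >= n_target && is.null(edges_target)) break
      iter <- iter + 1L
      if (iter > max_iter) break  # saturated simple graph; stop growing
      r <- runif(1)
      if (r < alpha) {
        w <- pick(indeg + delta_in)
        nv <- nv + 1L
        indeg <- c(indeg, 0); outdeg <- c(outdeg, 0)
        v <- nv
        from <- c(from, v); to <- c(to, w)
        outdeg[v] <- outdeg[v] + 1; indeg[w] <- indeg[w] + 1
        assign(paste(v, w), TRUE, envir = has_edge)
      } else if (r < alpha + beta) {
        ok <- FALSE
        for (try in 1:50) {
          v <- pick(outdeg + delta_out)
          w <- pick(indeg + delta_in)
          if (v != w && !exists(paste(v, w), envir = has_edge)) { ok <- TRUE; break }
        }
        if (!ok) next
        from <- c(from, v); to <- c(to, w)
        outdeg[v] <- outdeg[v] + 1; indeg[w] <- indeg[w] + 1
        assign(paste(v, w), TRUE, envir = has_edge)
      } else {
        v <- pick(outdeg + delta_out)
        nv <- nv + 1L
        indeg <- c(indeg, 0); outdeg <- c(outdeg, 0)
        w <- nv
        from <- c(from, v); to <- c(to, w)
        outdeg[v] <- outdeg[v] + 1; indeg[w] <- indeg[w] + 1
        assign(paste(v, w), TRUE, envir = has_edge)
      }
    }
  })
  ids <- default_ids(nv)
  neural_graph(cbind(ids[from], ids[to]), nodes = ids, directed = TRUE)
}
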