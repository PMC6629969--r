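# The forward model: utility evaluation, pairwise-stability checking,
# degree-rank node mapping and the add/delete evolution dynamics.

#' Utility-function coefficients
#'
#' The six weights of the linear neuron utility: `alpha` on the soma
#' distance `D_ij`, `beta` on the birth-time difference `B_ij` (both active
#' only when the pair is linked), `lambda` on the node's average shortest
#' path `S_i`, `rho` on PageRank `P_i`, `theta` on closeness `C_i` and
#' `omega` on betweenness `Be_i`.
#'
#' @param alpha,beta,lambda,rho,theta,omega finite numeric weights.
#' @return a named numeric vector of class `utility_coefficients`.
#' @export
utility_coefficients <- function(alpha = 0, beta = 0, lambda = 0,
                                 rho = 0, theta = 0, omega = 0) {
  x <- c(alpha = alpha, beta = beta, lambda = lambda,
         rho = rho, theta = theta, omega = omega)
  if (any(!is.finite(x))) stop("coefficients must be finite")
  structure(x, class = "utility_coefficients")
}

#' @noRd
as_coeffs <- function(x) {
  if (inherits(x, "utility_coefficients")) return(unclass(x))
  x <- unlist(x)
  if (length(x) != 6L) stop("need six utility coefficients")
  if (is.null(names(x)) || !all(COEF_NAMES %in% names(x))) names(x) <- COEF_NAMES
  x <- x[COEF_NAMES]
  if (any(!is.finite(x))) stop("coefficients must be finite")
  x
}

#' Evaluate the neuron utility function
#'
#' Computes the linear utility of a neuron against one partner:
#' `u = 1[linked] * (alpha * D + beta * B) + lambda * S + rho * P +
#' theta * C + omega * Be`. The indicator realizes the convention that the
#' link-cost terms (distance, birth-time difference) vanish when the link
#' is absent. An undefined `S` (isolated node, `NA`) drops the `lambda`
#' term with a warning.
#'
#' @param features named numeric vector (or list) with entries `D`, `B`,
#'   `S`, `P`, `C`, `Be`; see [pair_features()].
#' @param linked logical: is the pair linked in the evaluated state?
#' @param coeffs a [utility_coefficients()] vector.
#' @return a single numeric utility.
#' @examples
#' co <- utility_coefficients(alpha = -1, beta = -1, lambda = -0.02344,
#'                            theta = -1)
#' utility(c(D = 10, B = 5, S = 2, P = 0.1, C = 0.4, Be = 0.05),
#'         linked = TRUE, coeffs = co)
#' @export
utility <- function(features, linked, coeffs) {
  co <- as_coeffs(coeffs)
  f <- unlist(features)[FEATURE_NAMES]
  if (is.na(f[["S"]])) {
    warning("S undefined (isolated node); lambda term excluded")
    f[["S"]] <- 0
  }
  link_part <- if (linked) co[["alpha"]] * f[["D"]] + co[["beta"]] * f[["B"]] else 0
  unname(link_part + co[["lambda"]] * f[["S"]] + co[["rho"]] * f[["P"]] +
           co[["theta"]] * f[["C"]] + co[["omega"]] * f[["Be"]])
}

#' Pair features for one endpoint
#'
#' Collects the inputs of [utility()] for node `i` facing partner `j` in
#' the current graph: the symmetric pair attributes `D` (Euclidean soma
#' distance) and `B` (absolute birth-time difference) plus the structural
#' features of `i` from [node_features()].
#'
#' @param graph a neural graph.
#' @param attrs attribute table covering both nodes.
#' @param i,j node ids.
#' @return named numeric vector `c(D, B, S, P, C, Be)`.
#' @export
pair_features <- function(graph, attrs, i, j) {
  r <- match(c(i, j), attrs$neuron_id)
  if (anyNA(r)) stop("attributes missing for node(s): ",
                     paste(c(i, j)[is.na(r)], collapse = ", "))
  p <- as.matrix(attrs[r, c("x_um", "y_um", "z_um")])
  nf <- node_features(graph, i)
  c(D = sqrt(sum((p[1, ] - p[2, ])^2)),
    B = abs(attrs$birth_time_min[r[1]] - attrs$birth_time_min[r[2]]),
    nf)
}

# Internal: per-pair utility deltas (linked-state minus unlinked-state) for
# both endpoints, as delta %*% coeffs over the active features.
#' @noRd
pair_deltas <- function(A, i, j, Dm, Bm, co, need, add_dir) {
  ps <- pair_state_features(A, i, j, Dm, Bm, need, add_dir)
  list(linked = ps$linked, du = as.vector(ps$delta %*% co), delta = ps$delta)
}

#' Check pairwise stability of a network
#'
#' A network is pairwise stable when no neuron strictly gains by dropping
#' one of its links (deletion is unilateral) and no unlinked pair can be
#' added such that one endpoint strictly gains while the other does not
#' lose. Every unordered pair is examined by toggling the pair's link and
#' comparing both endpoints' utilities between the two states; violations
#' are reported with their utility deltas.
#'
#' For the hypothetical added link of an unlinked pair, the edge direction
#' is taken lexicographically (smaller id to larger id); direction only
#' matters when `rho != 0`, since all other structural features are
#' computed on the undirected projection.
#'
#' @param graph a neural graph.
#' @param attrs attribute table covering all nodes.
#' @param coeffs a [utility_coefficients()] vector.
#' @param tol strictness tolerance: a gain is strict when it exceeds `tol`.
#' @return an object of class `stability_report`: list with `stable`
#'   (logical), `violations` (data frame: pair, type, both deltas) and
#'   `n_pairs`.
#' @export
is_pairwise_stable <- function(graph, attrs, coeffs, tol = 1e-12) {
  validate_neural_graph(graph)
  co <- as_coeffs(coeffs)
  A <- adj_from_graph(graph)
  ids <- rownames(A)
  am <- attr_matrices(attrs, ids)
  need <- needed_features(co)
  prs <- upper_pairs(nrow(A))
  viol <- list()
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    pd <- pair_deltas(A, i, j, am$D, am$B, co, need, "low_to_high")
    if (pd$linked) {
      # deletion gain for endpoint e is -du[e]
      if (any(-pd$du > tol)) {
        viol[[length(viol) + 1L]] <- data.frame(
          i = ids[i], j = ids[j], type = "delete_gain",
          du_i = -pd$du[1], du_j = -pd$du[2])
      }
    } else {
      # addition blocked unless one endpoint strictly gains and the other
      # at least weakly gains
      if ((pd$du[1] > tol && pd$du[2] >= -tol) ||
          (pd$du[2] > tol && pd$du[1] >= -tol)) {
        viol[[length(viol) + 1L]] <- data.frame(
          i = ids[i], j = ids[j], type = "add_blocking",
          du_i = pd$du[1], du_j = pd$du[2])
      }
    }
  }
  violations <- if (length(viol) > 0L) do.call(rbind, viol) else
    data.frame(i = character(), j = character(), type = character(),
               du_i = numeric(), du_j = numeric())
  structure(list(stable = nrow(violations) == 0L, violations = violations,
                 n_pairs = nrow(prs)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Pairwise stability:", if (x$stable) "stable" else
    paste0("unstable (", nrow(x$violations), " violating pair(s))"), "\n")
  if (!x$stable) print(head(x$violations, 10))
  invisible(x)
}

#' Map base-network nodes onto reference nodes by degree rank
#'
#' Pairs the nodes of two equally sized graphs by ascending total
#' (in + out) degree, ties broken lexicographically by node id. Used to
#' transfer soma positions and birth times from the reference connectome
#' onto a degree-matched random base network before the game is played.
#'
#' @param base,reference neural graphs with equal node counts.
#' @return named character vector: `mapping[base_id] == reference_id`.
#' @export
map_nodes_by_degree <- function(base, reference) {
  nb <- igraph::vcount(base)
  if (nb != igraph::vcount(reference)) {
    stop("node counts differ (", nb, " vs ", igraph::vcount(reference), ")")
  }
  rank_ids <- function(g) {
    d <- igraph::degree(g, mode = "all")
    names(d)[order(d, names(d))]
  }
  setNames(rank_ids(reference), rank_ids(base))
}

#' Transfer attributes through a node mapping
#'
#' Builds an attribute table for the base network's node ids from the
#' reference attributes, via a [map_nodes_by_degree()] mapping.
#'
#' @param attrs reference attribute table.
#' @param mapping named character vector from base ids to reference ids.
#' @return attribute table whose `neuron_id` column holds the base ids.
#' @export
remap_attributes <- function(attrs, mapping) {
  r <- match(unname(mapping), attrs$neuron_id)
  if (anyNA(r)) stop("mapping targets missing from attributes")
  out <- attrs[r, ]
  out$neuron_id <- names(mapping)
  rownames(out) <- NULL
  out
}

#' Evolve a network to pairwise stability
#'
#' Plays the link-formation game on `base`: repeated sweeps over all
#' unordered node pairs in seeded-random order. A linked pair is deleted
#' when at least one endpoint strictly gains from deletion (deletion is a
#' unilateral decision; set `deletion_rule = "both"` to require both). An
#' unlinked pair is added when both endpoints strictly gain. The game stops
#' when a full sweep makes no move (converged) or after `max_sweeps`.
#'
#' The game acts on unordered pairs: a pair counts as linked when any
#' directed edge exists between them, deletion removes all such edges, and
#' an added link is a single directed edge whose direction is chosen by
#' `edge_direction` (`"coin"`: seeded fair coin flip; `"low_to_high"`:
#' lexicographic; `"both"`: reciprocal edges).
#'
#' @param base a neural graph (the base network).
#' @param attrs attribute table covering all nodes of `base` (typically via
#'   [remap_attributes()]).
#' @param coeffs a [utility_coefficients()] vector.
#' @param seed integer seed controlling sweep order and coin flips.
#' @param max_sweeps sweep budget.
#' @param deletion_rule `"either"` (unilateral, default) or `"both"`.
#' @param edge_direction direction convention for added links.
#' @param tol strictness tolerance for utility comparisons.
#' @param verbose log one line per sweep.
#' @return an object of class `evolution_result`: list with `graph` (the
#'   final network), `moves` (data frame: sweep, i, j, action `L`/`D`,
#'   utility deltas), `converged` and `sweeps`.
#' @export
evolve <- function(base, attrs, coeffs, seed = 1L, max_sweeps = 50L,
                   deletion_rule = c("either", "both"),
                   edge_direction = c("coin", "low_to_high", "both"),
                   tol = 1e-12, verbose = FALSE) {
  deletion_rule <- match.arg(deletion_rule)
  edge_direction <- match.arg(edge_direction)
  validate_neural_graph(base)
  co <- as_coeffs(coeffs)
  A <- adj_from_graph(base)
  ids <- rownames(A)
  am <- attr_matrices(attrs, ids)
  need <- needed_features(co)
  prs <- upper_pairs(nrow(A))
  moves <- list()
  converged <- FALSE
  sweeps <- 0L
  withr::with_seed(as.integer(seed), {
    for (sweep in seq_len(max_sweeps)) {
      sweeps <- sweep
      n_moves <- 0L
      for (r in sample.int(nrow(prs))) {
        i <- prs[r, 1]; j <- prs[r, 2]
        linked <- A[i, j] || A[j, i]
        if (linked) {
          pd <- pair_deltas(A, i, j, am$D, am$B, co, need, "low_to_high")
          gain <- -pd$du
          del <- if (deletion_rule == "either") any(gain > tol) else all(gain > tol)
          if (del) {
            A <- drop_pair_edges(A, i, j)
            n_moves <- n_moves + 1L
            moves[[length(moves) + 1L]] <- data.frame(
              sweep = sweep, i = ids[i], j = ids[j], action = "D",
              du_i = gain[1], du_j = gain[2])
          }
        } else {
          dir <- switch(edge_direction,
                        coin = if (runif(1) < 0.5) "i_to_j" else "j_to_i",
                        low_to_high = "low_to_high",
                        both = "both")
          pd <- pair_deltas(A, i, j, am$D, am$B, co, need, dir)
          if (all(pd$du > tol)) {
            A <- add_pair_edge(A, i, j, dir)
            n_moves <- n_moves + 1L
            moves[[length(moves) + 1L]] <- data.frame(
              sweep = sweep, i = ids[i], j = ids[j], action = "L",
              du_i = pd$du[1], du_j = pd$du[2])
          }
        }
      }
      if (verbose) {
        message("sweep ", sweep, ": ", n_moves, " move(s), ",
                sum(A), " directed edge(s)")
      }
      if (n_moves == 0L) {
        converged <- TRUE
        break
      }
    }
  })
  move_log <- if (length(moves) > 0L) do.call(rbind, moves) else
    data.frame(sweep = integer(), i = character(), j = character(),
               action = character(), du_i = numeric(), du_j = numeric())
  idx <- which(A, arr.ind = TRUE)
  g <- neural_graph(cbind(ids[idx[, 1]], ids[idx[, 2]]), nodes = ids,
                    directed = TRUE)
  structure(list(graph = g, moves = move_log, converged = converged,
                 sweeps = sweeps),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("Evolution: ", nrow(x$moves), " move(s) over ", x$sweeps, " sweep(s); ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  cat("Final network: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}
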