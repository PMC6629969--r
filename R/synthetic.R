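# Fully synthetic attributed networks, including ground-truth
# pairwise-stable networks under known coefficients, so the whole modelling
# chain is testable without any external connectome data.

#' Synthetic neuron attributes
#'
#' Draws soma positions uniformly in a cubic box and birth times either
#' uniformly or from a two-component mixture (a crude stand-in for an
#' early/late neurogenesis split; a convenience, not a biological claim).
#' The default unit scales keep all six utility features of order one,
#' which is the regime in which the linear utility produces non-trivial
#' equilibria.
#'
#' @param n node count.
#' @param volume box edge length (positions are uniform in `[0, volume]^3`).
#' @param birth_time_range birth times span `[0, birth_time_range]`.
#' @param birth_time_mode `"uniform"` or `"bimodal"` (60% in the lower
#'   third, 40% in the upper third of the range).
#' @param seed integer seed; the table is deterministic per seed.
#' @param ids optional node ids.
#' @return attribute data frame (see [read_attributes()]).
#' @export
synth_attributes <- function(n, volume = 1, birth_time_range = 1,
                             birth_time_mode = c("uniform", "bimodal"),
                             seed = 1L, ids = NULL) {
  birth_time_mode <- match.arg(birth_time_mode)
  if (is.null(ids)) ids <- default_ids(n)
  if (n == 0L) {
    return(data.frame(neuron_id = character(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      birth_time_min = numeric()))
  }
  withr::with_seed(as.integer(seed), {
    pos <- matrix(runif(3 * n, 0, volume), n, 3)
    bt <- if (birth_time_mode == "uniform") {
      runif(n, 0, birth_time_range)
    } else {
      early <- runif(n) < 0.6
      ifelse(early, runif(n, 0, birth_time_range / 3),
             runif(n, 2 * birth_time_range / 3, birth_time_range))
    }
  })
  data.frame(neuron_id = ids, x_um = pos[, 1], y_um = pos[, 2],
             z_um = pos[, 3], birth_time_min = bt)
}

#' Synthetic reference network with heavy-tailed degrees
#'
#' Emulates the shape of a small connectome: in- and out-degree sequences
#' are drawn from a discretized log-normal (heavy-tailed), capped at
#' `n - 1`, their sums equalized by seeded unit increments, and the pair is
#' realized exactly by [havel_hakimi_directed()]; attributes come from
#' [synth_attributes()].
#'
#' @param n node count.
#' @param meanlog,sdlog log-normal parameters of the degree draw.
#' @param seed integer seed.
#' @param ... further arguments to [synth_attributes()].
#' @return list with `graph`, `attrs`, `in_seq`, `out_seq`.
#' @export
synth_reference_network <- function(n = 131L, meanlog = 1.6, sdlog = 0.6,
                                    seed = 1L, ...) {
  for (attempt in 0:19) {
    s <- as.integer(seed) + attempt * 1009L
    seqs <- withr::with_seed(s, {
      draw <- function() pmin(round(rlnorm(n, meanlog, sdlog)), n - 1L)
      bump <- function(x) {
        k <- which(x < n - 1L)
        idx <- if (length(k) == 1L) k else sample(k, 1L)
        x[idx] <- x[idx] + 1L
        x
      }
      si <- draw(); so <- draw()
      # equalize sums by seeded unit increments on the smaller-sum sequence
      while (sum(si) != sum(so)) {
        if (sum(si) < sum(so)) si <- bump(si) else so <- bump(so)
      }
      list(si = as.integer(si), so = as.integer(so))
    })
    g <- tryCatch(havel_hakimi_directed(seqs$si, seqs$so, seed = s),
                  error = function(e) NULL)
    if (!is.null(g)) {
      attrs <- synth_attributes(n, seed = s, ...)
      return(list(graph = g, attrs = attrs,
                  in_seq = seqs$si, out_seq = seqs$so))
    }
  }
  stop("could not draw a di-graphical degree sequence in 20 attempts")
}

#' Synthetic pairwise-stable network under known coefficients
#'
#' Ground-truth generator for validating the inverse model: starts from a
#' sparse directed Erdos-Renyi graph over the supplied attribute table's
#' nodes and runs [evolve()] under `true_coeffs` until convergence. The
#' returned graph is pairwise stable under `true_coeffs` by the fixed-point
#' property of the dynamics; non-convergence within `max_sweeps` is an
#' error (callers building fixtures retry with another seed).
#'
#' @param attrs attribute table (defines the node set).
#' @param true_coeffs a [utility_coefficients()] vector.
#' @param init_p edge probability of the sparse random initial graph.
#' @param seed integer seed (initial graph, sweep order, coin flips).
#' @param max_sweeps sweep budget passed to [evolve()].
#' @param ... further arguments to [evolve()].
#' @return the stable neural graph, with the full `evolution_result`
#'   attached as attribute `"evolution"`.
#' @export
synth_stable_network <- function(attrs, true_coeffs, init_p = 0.08,
                                 seed = 1L, max_sweeps = 60L, ...) {
  ids <- sort(as.character(attrs$neuron_id))
  init <- erdos_renyi_directed(length(ids), init_p, seed = as.integer(seed),
                               ids = ids)
  res <- evolve(init, attrs, true_coeffs, seed = as.integer(seed) + 1L,
                max_sweeps = max_sweeps, ...)
  if (!res$converged) {
    stop("evolution did not converge within ", max_sweeps, " sweeps")
  }
  g <- res$graph
  attr(g, "evolution") <- res
  g
}
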