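# All generators are seed-deterministic and reference-matched; the directed
# Havel-Hakimi realization is exact.

test_that("directed Havel-Hakimi realizes di-graphical sequences exactly", {
  cases <- list(
    list(i = c(0, 0, 0), o = c(0, 0, 0)),
    list(i = c(1, 1, 0), o = c(0, 1, 1)),
    list(i = c(2, 1, 1), o = c(1, 2, 1)),
    list(i = c(3, 1, 0, 0), o = c(1, 1, 1, 1))
  )
  for (cs in cases) {
    for (s in 1:5) {
      g <- havel_hakimi_directed(cs$i, cs$o, seed = s)
      ids <- sort(igraph::V(g)$name)
      expect_equal(unname(igraph::degree(g, ids, mode = "in")), cs$i)
      expect_equal(unname(igraph::degree(g, ids, mode = "out")), cs$o)
      expect_true(igraph::is_simple(g))
    }
  }
  # randomized heavy-tailed sequences drawn from realized digraphs are
  # always di-graphical and must be realized exactly
  for (s in 1:10) {
    h <- rand_digraph(25, 0.15, seed = s)
    ids <- sort(igraph::V(h)$name)
    iseq <- unname(igraph::degree(h, ids, mode = "in"))
    oseq <- unname(igraph::degree(h, ids, mode = "out"))
    g <- havel_hakimi_directed(iseq, oseq, seed = s)
    ids2 <- sort(igraph::V(g)$name)
    expect_equal(unname(igraph::degree(g, ids2, mode = "in")), iseq)
    expect_equal(unname(igraph::degree(g, ids2, mode = "out")), oseq)
  }
})

test_that("Havel-Hakimi feasibility matches brute-force enumeration on 3 nodes", {
  # oracle: enumerate all 64 labelled simple 3-node digraphs and collect the
  # set of realizable (in, out) sequence pairs
  pairs <- expand.grid(from = 1:3, to = 1:3)
  pairs <- pairs[pairs$from != pairs$to, ]
  realizable <- new.env(hash = TRUE)
  for (mask in 0:63) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    iseq <- tabulate(pairs$to[sel], 3)
    oseq <- tabulate(pairs$from[sel], 3)
    assign(paste(c(iseq, oseq), collapse = ","), TRUE, envir = realizable)
  }
  grid <- expand.grid(i1 = 0:2, i2 = 0:2, i3 = 0:2, o1 = 0:2, o2 = 0:2, o3 = 0:2)
  grid <- grid[grid$i1 + grid$i2 + grid$i3 == grid$o1 + grid$o2 + grid$o3, ]
  for (r in seq_len(nrow(grid))) {
    iseq <- as.integer(grid[r, 1:3]); oseq <- as.integer(grid[r, 4:6])
    expected <- exists(paste(c(iseq, oseq), collapse = ","), envir = realizable)
    got <- !inherits(try(havel_hakimi_directed(iseq, oseq, seed = 1),
                         silent = TRUE), "try-error")
    expect_equal(got, expected,
                 label = paste("realizability of in =", paste(iseq, collapse = ","),
                               "out =", paste(oseq, collapse = ",")))
  }
})

test_that("non-di-graphical sequences are rejected", {
  expect_error(havel_hakimi_directed(c(3, 0, 0), c(1, 1, 1)), "di-graphical")
  expect_error(havel_hakimi_directed(c(1, 0, 0), c(1, 1, 1)), "di-graphical")
  expect_error(havel_hakimi_directed(c(1, 1), c(1, 1, 0)), "length")
})

test_that("directed Erdos-Renyi hits its boundary cases and binomial mean", {
  expect_equal(igraph::ecount(erdos_renyi_directed(5, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(erdos_renyi_directed(4, 1, seed = 1)), 12)
  counts <- vapply(1:30, function(s) {
    igraph::ecount(erdos_renyi_directed(131, 0.5, seed = s))
  }, numeric(1))
  mu <- 0.5 * 131 * 130
  se <- sqrt(131 * 130 * 0.25) / sqrt(30)
  expect_lt(abs(mean(counts) - mu), 4 * se)
})

test_that("distance-based Watts-Strogatz wires nearest neighbours then rewires", {
  # 7 equally spaced collinear somata, k = 2, no rewiring
  at <- data.frame(neuron_id = sprintf("n%d", 1:7), x_um = 1:7, y_um = 0,
                   z_um = 0, birth_time_min = 0)
  g <- watts_strogatz_distance(at, k = 2, rewire_p = 0, seed = 1)
  for (i in 2:6) {
    expect_true(igraph::are_adjacent(g, sprintf("n%d", i), sprintf("n%d", i - 1)))
    expect_true(igraph::are_adjacent(g, sprintf("n%d", i), sprintf("n%d", i + 1)))
  }
  expect_true(all(igraph::degree(g) >= 2))
  # rewiring moves edges but never deletes them
  at2 <- rand_attrs(20, seed = 3)
  g0 <- watts_strogatz_distance(at2, k = 4, rewire_p = 0, seed = 5)
  g1 <- watts_strogatz_distance(at2, k = 4, rewire_p = 1, seed = 5)
  expect_equal(igraph::ecount(g1), igraph::ecount(g0))
  expect_true(all(igraph::degree(g0) >= 4))
})

test_that("expected-degree graphs match the Chung-Lu edge probabilities", {
  expect_equal(igraph::ecount(expected_degree_graph(c(0, 0, 0), seed = 1)), 0)
  expect_equal(igraph::vcount(expected_degree_graph(5, seed = 1)), 1)
  # seq (2,2,2,2): p_uv = 0.5 for each of 6 pairs, mean degree 1.5
  degs <- vapply(1:500, function(s) {
    mean(igraph::degree(expected_degree_graph(c(2, 2, 2, 2), seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(degs) - 1.5), 0.1)
  expect_warning(expected_degree_graph(c(10, 10), seed = 1), "clipped")
})

test_that("power-law clustering growth has exact edge counts and closes triangles", {
  g <- powerlaw_cluster_graph(40, 3, triangle_p = 0, seed = 2)
  expect_equal(igraph::ecount(g), (40 - 3) * 3)
  expect_equal(igraph::vcount(powerlaw_cluster_graph(4, 3, 0.2, seed = 1)), 4)
  cl <- vapply(1:30, function(s) {
    c(igraph::transitivity(powerlaw_cluster_graph(131, 6, 0.2, seed = s),
                           type = "localaverage", isolates = "zero"),
      igraph::transitivity(powerlaw_cluster_graph(131, 6, 0, seed = s),
                           type = "localaverage", isolates = "zero"))
  }, numeric(2))
  expect_gt(mean(cl[1, ] - cl[2, ]), 0)
  expect_lt(stats::t.test(cl[1, ], cl[2, ], paired = TRUE)$p.value, 0.01)
})

test_that("directed scale-free growth shows preferential attachment structure", {
  # beta = 0: every event adds a node
  g <- scale_free_directed(50, alpha = 0.6, beta = 0, gamma = 0.4, seed = 1)
  expect_equal(igraph::vcount(g), 50)
  expect_equal(igraph::ecount(g), 3 + (50 - 3))
  # alpha = 1: all edges point into preferentially chosen existing nodes,
  # so the maximum in-degree sits in the initial seed set
  g1 <- scale_free_directed(60, alpha = 1, beta = 0, gamma = 0, seed = 4)
  top <- names(which.max(igraph::degree(g1, mode = "in")))
  expect_true(top %in% sprintf("v%03d", 1:3))
  # reference parameterization: heavy-tailed in-degrees
  ratios <- vapply(1:30, function(s) {
    g <- scale_free_directed(131, seed = s)
    d <- igraph::degree(g, mode = "in")
    max(d) / max(1, stats::median(d))
  }, numeric(1))
  expect_gt(mean(ratios > 3), 0.9)
  # edge budget stops growth
  gb <- scale_free_directed(1000, seed = 2, edges_target = 200)
  expect_gte(igraph::ecount(gb), 200)
  expect_error(scale_free_directed(10, alpha = 0.5, beta = 0.2, gamma = 0.5),
               "alpha \\+ beta \\+ gamma")
})

test_that("every generator is seed-deterministic", {
  at <- rand_attrs(15, seed = 11)
  gens <- list(
    function(s) havel_hakimi_directed(rep(2, 10), rep(2, 10), seed = s),
    function(s) erdos_renyi_directed(15, 0.3, seed = s),
    function(s) watts_strogatz_distance(at, k = 3, rewire_p = 0.5, seed = s),
    function(s) expected_degree_graph(rep(3, 12), seed = s),
    function(s) powerlaw_cluster_graph(20, 3, 0.3, seed = s),
    function(s) scale_free_directed(30, seed = s)
  )
  edge_key <- function(g) {
    sort(apply(igraph::as_edgelist(g), 1, paste, collapse = ">"))
  }
  for (gen in gens) {
    expect_identical(edge_key(gen(42)), edge_key(gen(42)))
    expect_silent(validate_neural_graph(gen(43)))
  }
})
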