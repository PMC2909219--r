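test_that("articulation decomposition follows the degree rule", {
  # path graph: articulation vertices all have two neighbors, no split
  p <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(p)$J <- 1L
  expect_length(scafopt::decompose(p), 1)
  # two triangles sharing a degree-4 vertex: split into the triangles
  g <- igraph::make_graph(~ a - b, b - v, a - v, v - c, c - d, d - v)
  igraph::E(g)$J <- 1L
  ps <- scafopt::decompose(g)
  expect_length(ps, 2)
  expect_true(all(vapply(ps, function(x) "v" %in% igraph::V(x)$name, TRUE)))
  # random trees: every vertex of degree > 2 in a tree is an articulation
  # point, so all non-reducible pieces are simple paths; brute-force check
  # that no piece retains a splittable vertex
  set.seed(2)
  for (r in 1:20) {
    tr <- igraph::sample_tree(sample(5:12, 1))
    igraph::V(tr)$name <- sprintf("t%02d", seq_len(igraph::vcount(tr)))
    igraph::E(tr)$J <- 1L
    for (pc in scafopt::decompose(tr)) {
      expect_true(all(igraph::degree(pc) <= 2))
      ap <- igraph::articulation_points(pc)
      if (length(ap)) expect_true(all(igraph::degree(pc, ap) <= 2))
    }
  }
})

test_that("breadth-first layers only connect adjacent layers", {
  p <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  igraph::E(p)$J <- 1L
  expect_equal(lengths(layer_sets(p, "a")), rep(1L, 5))
  st <- igraph::make_star(7, "undirected", center = 1)
  igraph::V(st)$name <- c("hub", sprintf("s%d", 1:6))
  igraph::E(st)$J <- 1L
  expect_equal(lengths(layer_sets(st, "hub")), c(1L, 6L))
  set.seed(3)
  for (r in 1:10) {
    g <- random_ising_graph(sample(5:12, 1))
    ls <- layer_sets(g)
    lay <- integer(igraph::vcount(g))
    names(lay) <- igraph::V(g)$name
    for (k in seq_along(ls)) lay[ls[[k]]] <- k
    el <- igraph::as_edgelist(g)
    expect_true(all(abs(lay[el[, 1]] - lay[el[, 2]]) <= 1))
  }
})

test_that("layered dynamic programming is exact on random small graphs", {
  g1 <- igraph::make_graph(~ a - b); igraph::E(g1)$J <- 3L
  r1 <- solve_dp(g1)
  expect_equal(r1$energy, -3)
  expect_equal(unname(r1$S["a"] * r1$S["b"]), 1)
  gt <- igraph::make_graph(~ a - b, b - c, a - c)
  igraph::E(gt)$J <- c(1L, 1L, -1L)
  expect_equal(solve_dp(gt)$energy, -1)  # frustrated triangle
  set.seed(4)
  for (r in 1:60) {
    g <- random_ising_graph(sample(3:12, 1))
    r_dp <- solve_dp(g, layer_cap = 12)
    expect_false(is.null(r_dp))
    expect_equal(r_dp$energy, brute_ising(g))
    # canonical flip: first vertex by name is +1
    expect_equal(unname(r_dp$S[sort(names(r_dp$S))[1]]), 1L)
  }
})

test_that("annealing reaches the exact optimum on small graphs and is
           deterministic under a fixed seed", {
  set.seed(5)
  # planted satisfiable instance: E_min is reachable
  for (r in 1:10) {
    n <- 30
    g <- random_ising_graph(n, p = 0.15)
    planted <- sample(c(-1L, 1L), n, TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$J <- abs(igraph::E(g)$J) * planted[el[, 1]] * planted[el[, 2]]
    r_sa <- solve_sa(g, seed = r)
    expect_equal(r_sa$energy, -sum(abs(igraph::E(g)$J)))
  }
  for (r in 1:20) {
    g <- random_ising_graph(sample(3:10, 1))
    r_sa <- solve_sa(g, seed = 100 + r)
    expect_equal(r_sa$energy, brute_ising(g))
  }
  g <- random_ising_graph(12)
  a <- solve_sa(g, seed = 7); b <- solve_sa(g, seed = 7)
  expect_identical(a$S, b$S)
  expect_identical(a$energy, b$energy)
})

test_that("decomposition plus merging preserves the global optimum", {
  set.seed(6)
  cfg <- scaf_config(libraries = scaf_library("l", "solid_mate", 1000))
  for (r in 1:30) {
    # build a graph with articulation structure: chain of small blobs
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    g1 <- random_ising_graph(n1); g2 <- random_ising_graph(n2)
    e1 <- igraph::as_data_frame(g1); e2 <- igraph::as_data_frame(g2)
    e2$from <- sub("^v", "w", e2$from); e2$to <- sub("^v", "w", e2$to)
    # share one vertex to create an articulation point
    e2$from[e2$from == "w01"] <- "v01"; e2$to[e2$to == "w01"] <- "v01"
    edges <- rbind(e1, e2)
    gg <- igraph::graph_from_data_frame(edges, directed = FALSE)
    if (igraph::components(gg)$no != 1) next
    graph <- edge_graph(data.frame(ci = edges$from, cj = edges$to,
                                   J = as.integer(edges$J)))
    ao <- assign_orientations(graph, cfg)
    expect_equal(ao$energy, brute_ising(gg))
    expect_equal(ao$energy, ao$E_min + 2 * sum(abs(
      graph$edges$J[ao$violated])))
  }
})

test_that("planted flipped edges are recovered as the violated set", {
  set.seed(8)
  cfg <- scaf_config(libraries = scaf_library("l", "solid_mate", 1000))
  # ring of 20 with chords: consistent signs from a planted assignment,
  # then flip 5% adversarially
  n <- 20
  edges <- data.frame(ci = sprintf("v%02d", 1:n),
                      cj = sprintf("v%02d", c(2:n, 1)))
  # chords give every vertex degree 4 so that no single flip can trade a
  # planted-flip violation for an equal-weight one
  chords <- data.frame(ci = sprintf("v%02d", 1:n),
                       cj = sprintf("v%02d", c(3:n, 1, 2)))
  edges <- rbind(edges, chords)
  planted <- stats::setNames(sample(c(-1L, 1L), n, TRUE),
                             sprintf("v%02d", 1:n))
  edges$J <- 5L * planted[edges$ci] * planted[edges$cj]
  flip <- sample(nrow(edges), 2)
  edges$J[flip] <- -edges$J[flip]
  graph <- edge_graph(edges)
  ao <- assign_orientations(graph, cfg)
  expect_equal(unname(sort(which(ao$violated))), sort(flip))
  # recovered assignment equals the planted one up to a global flip
  rel <- ao$S * planted[names(ao$S)]
  expect_true(all(rel == rel[1]))
})

test_that("two components are solved independently and energies add", {
  edges <- data.frame(ci = c("a", "b", "x"), cj = c("b", "c", "y"),
                      J = c(2L, -1L, 4L))
  cfg <- scaf_config(libraries = scaf_library("l", "solid_mate", 1000))
  ao <- assign_orientations(edge_graph(edges), cfg)
  expect_equal(ao$energy, -7)
  expect_equal(sum(ao$violated), 0)
})
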